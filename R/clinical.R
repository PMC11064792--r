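#' Standard Gesell milestone ages, in months
#'
#' The 24 developmental milestones of the schedule: 4 to 56 weeks (converted
#' at 4.345 weeks/month) then 15 to 72 months.
#'
#' @return Numeric vector of 24 milestone ages in months.
#' @export
gesell_milestones <- function() {
  weeks <- c(4, 8, 12, 16, 20, 24, 28, 32, 40, 44, 48, 52, 56)
  months <- c(15, 18, 21, 24, 30, 36, 42, 48, 54, 60, 72)
  c(weeks / 4.345, months)
}

#' Gesell developmental age from milestone passes
#'
#' Pass-weighted mean of milestone ages: `DA = sum(W_i * N_i) / sum(N_i)`,
#' where `N_i` items were passed at milestone age `W_i` (months).
#'
#' @param passes Named numeric vector: names are milestone ages in months,
#'   values are non-negative integer counts of items passed.
#' @return Developmental age in months.
#' @export
compute_developmental_age <- function(passes) {
  w <- as.numeric(names(passes))
  n <- as.numeric(passes)
  if (any(is.na(w))) stop("passes must be named by milestone age in months")
  if (any(n < 0)) stop("pass counts must be non-negative")
  if (sum(n) == 0) stop("no items passed: developmental age undefined")
  sum(w * n) / sum(n)
}

#' Developmental quotient
#'
#' `DQ = 100 * DA / CA`.
#'
#' @param da Developmental age, months.
#' @param ca Chronological age, months (> 0).
#' @return DQ score.
#' @export
compute_dq <- function(da, ca) {
  if (ca <= 0) stop("chronological age must be > 0")
  100 * da / ca
}

#' Classify a developmental quotient
#'
#' DQ < 76: developmental delay; 76 <= DQ <= 85: borderline (slightly below
#' the delay threshold); DQ >= 86: normal development.
#'
#' @param dq DQ score(s), >= 0.
#' @return Character vector in {"delay", "borderline", "normal"}.
#' @export
classify_dq <- function(dq) {
  if (any(dq < 0)) stop("DQ must be >= 0")
  ifelse(dq < 76, "delay", ifelse(dq < 86, "borderline", "normal"))
}

#' Score the Childhood Autism Rating Scale
#'
#' Sum of the 15 item scores; severity bands: total < 30 "not_autistic",
#' 30-36 "mild_moderate", > 36 "severe". Half-point item scores are admitted
#' (standard CARS practice).
#'
#' @param item_scores Numeric vector of exactly 15 scores, each in
#'   {1, 1.5, 2, 2.5, 3, 3.5, 4}.
#' @return List with `total` and `severity`.
#' @export
score_cars <- function(item_scores) {
  if (length(item_scores) != 15)
    stop("CARS requires exactly 15 item scores, got ", length(item_scores))
  if (!all(item_scores %in% seq(1, 4, by = 0.5)))
    stop("CARS item scores must lie in {1, 1.5, ..., 4}")
  total <- sum(item_scores)
  severity <- if (total < 30) "not_autistic"
              else if (total <= 36) "mild_moderate" else "severe"
  list(total = total, severity = severity)
}

#' Read clinical score tables
#'
#' `read_gesell_csv` expects long format
#' (`id, domain, milestone_months, n_passed, ca_months`) and returns per
#' id-by-domain DA, DQ and band. `read_cars_csv` expects
#' (`id, item1..item15`) and returns totals and severity. `read_pep3_csv`
#' expects (`id, cvp, el, rl, fm, gm, vmi`) and returns it validated; the
#' PEP-3 performance subscales are containers joined for correlation
#' analysis, with no derived score.
#'
#' @param path CSV path.
#' @return data.frame of derived scores (Gesell/CARS) or validated subscales
#'   (PEP-3).
#' @export
read_gesell_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "domain", "milestone_months", "n_passed", "ca_months")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("gesell csv missing columns: ",
                         paste(miss, collapse = ", "))
  out <- do.call(rbind, lapply(split(d, list(d$id, d$domain), drop = TRUE),
    function(g) {
      passes <- stats::setNames(g$n_passed, g$milestone_months)
      da <- compute_developmental_age(passes)
      dq <- compute_dq(da, g$ca_months[1])
      data.frame(id = g$id[1], domain = g$domain[1], da_months = da,
                 dq = dq, band = classify_dq(dq), stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' @rdname read_gesell_csv
#' @export
read_cars_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  items <- paste0("item", 1:15)
  miss <- setdiff(c("id", items), names(d))
  if (length(miss)) stop("cars csv missing columns: ",
                         paste(miss, collapse = ", "))
  res <- t(apply(d[items], 1, function(x) {
    s <- score_cars(as.numeric(x))
    c(total = s$total, severity = s$severity)
  }))
  data.frame(id = d$id, cars_total = as.numeric(res[, "total"]),
             cars_severity = res[, "severity"], stringsAsFactors = FALSE)
}

#' @rdname read_gesell_csv
#' @export
read_pep3_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "cvp", "el", "rl", "fm", "gm", "vmi")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("pep3 csv missing columns: ",
                         paste(miss, collapse = ", "))
  for (col in need[-1]) {
    if (any(d[[col]] < 0, na.rm = TRUE))
      stop("pep3 subscale '", col, "' has negative values")
  }
  d[need]
}
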