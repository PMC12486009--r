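#' Decile transform of exposure values
#'
#' Rank-based deciles: each value's average rank (ties share the mean
#' rank) is mapped to `ceiling(10 * rank / n)`.  The transform is monotone
#' and invariant under any strictly increasing transformation of the
#' input, and with `n = 10` distinct values yields exactly one unit per
#' decile.  A fully tied vector lands in a single decile.
#'
#' @param values Finite, numeric exposure values (one per areal unit).
#' @return Integer vector in `1:10`, same length as `values`.
#' @export
to_deciles <- function(values) {
  if (length(values) == 0) stop("to_deciles: empty input", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("to_deciles: values must be finite numbers", call. = FALSE)
  }
  as.integer(ceiling(10 * rank(values, ties.method = "average") /
                       length(values)))
}

check_pair <- function(a, b, what) {
  if (length(a) != length(b)) {
    stop(what, ": vectors differ in length (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
}

#' Fraction of units in good agreement
#'
#' Two decile assignments of a unit are in "good" agreement when they
#' differ by at most one decile; this returns the fraction of units for
#' which that holds.
#'
#' @param deciles_a,deciles_b Equal-length integer decile vectors.
#' @return A fraction in `[0, 1]`.
#' @export
good_agreement <- function(deciles_a, deciles_b) {
  check_pair(deciles_a, deciles_b, "good_agreement")
  if (length(deciles_a) == 0) {
    stop("good_agreement: empty input", call. = FALSE)
  }
  mean(abs(deciles_a - deciles_b) <= 1)
}

#' Cohen's Kappa between two decile assignments
#'
#' Unweighted chance-corrected exact-match agreement
#' `kappa = (po - pe) / (1 - pe)`, with `po` the observed exact-match
#' fraction and `pe = sum_k p_a(k) p_b(k)` the marginal chance agreement
#' over the decile categories.  When both raters are constant and equal
#' (`pe = 1`) agreement is perfect and 1 is returned.  A linear-weighted
#' variant (disagreement penalized proportionally to decile distance) is
#' available via `weighting = "linear"`.
#'
#' @inheritParams good_agreement
#' @param weighting `"unweighted"` (default) or `"linear"`.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(deciles_a, deciles_b,
                         weighting = c("unweighted", "linear")) {
  check_pair(deciles_a, deciles_b, "cohens_kappa")
  weighting <- match.arg(weighting)
  n <- length(deciles_a)
  if (n == 0) stop("cohens_kappa: empty input", call. = FALSE)
  cats <- sort(unique(c(deciles_a, deciles_b)))
  k <- length(cats)
  pa <- tabulate(match(deciles_a, cats), k) / n
  pb <- tabulate(match(deciles_b, cats), k) / n
  wmat <- if (weighting == "unweighted") {
    diag(k)
  } else {
    1 - abs(outer(cats, cats, "-")) / max(diff(range(cats)), 1)
  }
  obs <- wmat[cbind(match(deciles_a, cats), match(deciles_b, cats))]
  po <- mean(obs)
  pe <- sum(wmat * outer(pa, pb))
  if (abs(1 - pe) < 1e-12) return(1)
  (po - pe) / (1 - pe)
}

#' Kendall's tau-b between two ranked vectors
#'
#' Tie-corrected Kendall rank correlation,
#' `(C - D) / sqrt((n0 - n1) (n0 - n2))`, the appropriate variant for
#' decile data where ties are pervasive.  When either vector is fully
#' tied the coefficient is undefined; `NaN` is returned with a warning.
#'
#' @inheritParams good_agreement
#' @return Tau-b in `[-1, 1]`, or `NaN` for a fully tied vector.
#' @export
kendall_tau <- function(deciles_a, deciles_b) {
  check_pair(deciles_a, deciles_b, "kendall_tau")
  if (length(deciles_a) < 2) {
    stop("kendall_tau: need at least two observations", call. = FALSE)
  }
  if (stats::var(deciles_a) == 0 || stats::var(deciles_b) == 0) {
    warning("kendall_tau: a vector is fully tied; tau is undefined")
    return(NaN)
  }
  stats::cor(deciles_a, deciles_b, method = "kendall")
}

#' Decile table for one geographic level
#'
#' Transforms each column of an [compute_exposure_table()] result into
#' within-level deciles.
#'
#' @param exposure An `exposure_table` data frame.
#' @return A data frame of class `decile_table` with columns `level`,
#'   `unit_id`, `decile_ej`, `decile_density`, `decile_parcel`.
#' @export
decile_table <- function(exposure) {
  structure(data.frame(level = exposure$level, unit_id = exposure$unit_id,
                       decile_ej = to_deciles(exposure$ej_screen),
                       decile_density = to_deciles(exposure$aadt_density),
                       decile_parcel = to_deciles(exposure$parcel_proximity),
                       stringsAsFactors = FALSE),
            class = c("decile_table", "data.frame"))
}

#' Agreement of each candidate measure with the parcel reference
#'
#' For the EJ-Screen proximity and the AADT density in turn, computes the
#' good-agreement fraction, unweighted Cohen's Kappa and Kendall's tau-b
#' against the parcel truck-traffic proximity deciles.
#'
#' @param deciles A [decile_table()].
#' @return A data frame with one row per candidate measure: `level`,
#'   `measure`, `good_agreement_fraction`, `kappa`, `tau`, `n_units`.
#' @export
assess_agreement <- function(deciles) {
  ref <- deciles$decile_parcel
  rows <- lapply(c(ej_screen = "decile_ej", aadt_density = "decile_density"),
                 function(col) {
    cand <- deciles[[col]]
    data.frame(level = deciles$level[1],
               good_agreement_fraction = good_agreement(cand, ref),
               kappa = cohens_kappa(cand, ref),
               tau = kendall_tau(cand, ref),
               n_units = length(ref), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(level = out$level, measure = names(rows),
               out[, -1, drop = FALSE])
  rownames(out) <- NULL
  out
}
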