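# Pairwise covariation analysis for base-pair inference. The statistic is
# mutual information of the joint base distribution at two positions,
# calibrated against a Monte-Carlo null of unselected pools drawn from the
# doping model, with a pairing-consistency fraction reported alongside so
# that "covaries" and "covaries like a base pair" stay distinct. Mutant
# cycles score putative pairs from activity measurements.

# all-pairs MI matrix (bits) for an encoded pool with weights w.
# joint counts come from 16 cross-products of weighted indicator matrices.
mi_matrix <- function(m, w) {
  L <- ncol(m)
  total <- sum(w)
  X <- lapply(1:4, function(b) (m == b) * 1)
  Xw <- lapply(X, function(x) x * w)
  marg <- vapply(Xw, colSums, numeric(L)) / total    # L x 4 marginal freqs
  mi <- matrix(0, L, L)
  for (a in 1:4) {
    la <- log2(marg[, a])
    for (b in 1:4) {
      P <- crossprod(Xw[[a]], X[[b]]) / total        # joint freq of (a at i, b at j)
      lp <- outer(la, log2(marg[, b]), "+")
      term <- P * (log2(P) - lp)
      term[P == 0] <- 0
      mi <- mi + term
    }
  }
  mi <- pmax(mi, 0)
  diag(mi) <- NA_real_
  mi
}

#' Mutual information between two positions of a pool
#'
#' @param table A `sequence`/`count` tibble of uniform length.
#' @param i,j Distinct 1-based positions.
#' @param weighting `"reads"` (count-weighted, default) or `"unique"`.
#' @return MI in bits (non-negative, symmetric in `i`, `j`).
#' @export
mutual_information <- function(table, i, j, weighting = c("reads", "unique")) {
  weighting <- match.arg(weighting)
  L <- table_length(table)
  if (i == j) abort("`i` and `j` must differ")
  if (min(i, j) < 1L || max(i, j) > L) abort("positions out of range")
  m <- encode_seqs(table$sequence)[, c(i, j), drop = FALSE]
  w <- if (weighting == "reads") as.numeric(table$count) else
    rep(1, nrow(table))
  mi_matrix(m, w)[1L, 2L]
}

#' Pairing consistency of the double-deviant sequences at two positions
#'
#' Among reads deviating from the reference at both `i` and `j`, the
#' count-weighted fraction whose bases at (i, j) are complementary
#' (Watson-Crick, plus G-T/T-G when `allow_gu`). Compensatory double
#' mutations restoring complementarity are the signature of a base pair.
#'
#' @inheritParams mutual_information
#' @param reference Reference sequence.
#' @param allow_gu Accept G-T/T-G wobbles as complementary.
#' @return A one-row tibble with `fraction` (`NA` when no double-deviant
#'   exists — undefined, not zero), `n_double_deviant` (reads) and
#'   `defined`.
#' @export
pairing_consistency <- function(table, i, j, reference, allow_gu = TRUE) {
  L <- table_length(table)
  if (i == j) abort("`i` and `j` must differ")
  if (min(i, j) < 1L || max(i, j) > L) abort("positions out of range")
  if (nchar(reference) != L) abort("reference length does not match the table")
  ref <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  bi <- substr(table$sequence, i, i)
  bj <- substr(table$sequence, j, j)
  dd <- bi != ref[[i]] & bj != ref[[j]]
  n_dd <- sum(table$count[dd])
  if (n_dd == 0L) {
    return(tibble(fraction = NA_real_, n_double_deviant = 0L,
                  defined = FALSE))
  }
  comp <- pair_complementary(bi[dd], bj[dd], allow_gu = allow_gu)
  tibble(fraction = sum(table$count[dd][comp]) / n_dd,
         n_double_deviant = as.integer(n_dd), defined = TRUE)
}

#' Covariation scan with a doping-model Monte Carlo null
#'
#' Computes MI and pairing consistency for every position pair, then
#' compares each observed MI against `n_null` unselected pools of matched
#' read count drawn from the doping model (the "randomly chosen subsets of
#' the starting library" null). `null_p` is the fraction of null pools with
#' MI at least the observed value; q-values are Benjamini-Hochberg across
#' the L(L-1)/2 pairs.
#'
#' @param table A `sequence`/`count` tibble of uniform length.
#' @param model A [doping_model()] describing the starting library.
#' @param n_null Number of null pools (>= 100 for usable p resolution).
#' @param seed Integer seed for the null draws.
#' @param reference Reference for pairing consistency; defaults to the
#'   doping-model reference.
#' @param allow_gu Accept G-T/T-G wobbles in pairing consistency.
#' @param weighting `"reads"` or `"unique"`.
#' @return A tibble with columns `i`, `j`, `mi`, `pairing_consistency`,
#'   `n_double_deviant`, `null_p`, `q`, sorted by `null_p` then decreasing
#'   `mi`.
#' @export
covariation_scan <- function(table, model, n_null = 100L, seed = 1L,
                             reference = model$reference, allow_gu = TRUE,
                             weighting = c("reads", "unique")) {
  weighting <- match.arg(weighting)
  L <- table_length(table)
  if (n_null < 100L) abort("`n_null` must be at least 100")
  if (nchar(reference) != L || nchar(model$reference) != L) {
    abort("table, model reference and reference must share one length")
  }
  m <- encode_seqs(table$sequence)
  w <- if (weighting == "reads") as.numeric(table$count) else
    rep(1, nrow(table))
  obs <- mi_matrix(m, w)

  n_reads <- if (weighting == "reads") sum(table$count) else nrow(table)
  n_reads <- min(n_reads, 5000L)  # null pool size cap keeps scans tractable
  exceed <- matrix(0L, L, L)
  for (b in seq_len(n_null)) {
    null_seqs <- sample_pool_seqs(model, n_reads, seed = seed + b)
    null_mi <- mi_matrix(encode_seqs(null_seqs), rep(1, n_reads))
    exceed <- exceed + (null_mi >= obs)
  }

  ut <- which(upper.tri(obs), arr.ind = TRUE)
  res <- tibble(i = ut[, "row"], j = ut[, "col"],
                mi = obs[ut],
                null_p = exceed[ut] / n_null)
  pc <- purrr::map2(res$i, res$j, function(i, j) {
    pairing_consistency(table, i, j, reference, allow_gu = allow_gu)
  })
  res$pairing_consistency <- purrr::map_dbl(pc, "fraction")
  res$n_double_deviant <- purrr::map_int(pc, "n_double_deviant")
  res$q <- p.adjust(res$null_p, method = "BH")
  arrange(res[, c("i", "j", "mi", "pairing_consistency", "n_double_deviant",
                  "null_p", "q")],
          .data$null_p, desc(.data$mi))
}

#' Mutant-cycle interaction scoring
#'
#' For a double cycle the interaction ratio is
#' `R = (A_m12 * A_wt) / (A_m1 * A_m2)`: R >> 1 ("rescue") means the double
#' mutant is far more active than expected from multiplicative independence,
#' the signature of a restored base pair. Triple cycles use the analogous
#' inclusion-exclusion ratio over the 2^3 activity cube,
#' `R = (A_m123 * A_m1 * A_m2 * A_m3) / (A_m12 * A_m13 * A_m23 * A_wt)`.
#' Zero activities are floored at `floor_frac * A_wt` so ratios stay
#' defined; floored corners are flagged.
#'
#' @param acts A data frame with columns `label` and `activity`. Labels
#'   `wt`, `m1`, `m2`, `m12` are required for a double cycle; adding `m3`,
#'   `m13`, `m23`, `m123` makes it a triple cycle.
#' @param rescue_threshold Ratio at or above which the verdict is
#'   `"rescue"`.
#' @param independence_band Ratios within `[1/band, band]` are
#'   `"independent"`; below `1/band` is `"aggravating"`, otherwise
#'   `"interacting"`.
#' @param floor_frac Activity floor as a fraction of `A_wt`.
#' @return A one-row tibble with `order` (2 or 3), `ratio`, `verdict` and
#'   `floored` (labels whose activity was floored, comma-separated).
#' @export
mutant_cycle <- function(acts, rescue_threshold = 5, independence_band = 2,
                         floor_frac = 0.001) {
  if (!all(c("label", "activity") %in% names(acts))) {
    abort("`acts` needs columns `label` and `activity`")
  }
  a <- setNames(as.numeric(acts$activity), acts$label)
  need2 <- c("wt", "m1", "m2", "m12")
  missing2 <- setdiff(need2, names(a))
  if (length(missing2) > 0L) {
    abort(sprintf("missing mutant-cycle corner(s): %s",
                  paste(missing2, collapse = ", ")))
  }
  triple <- any(c("m3", "m13", "m23", "m123") %in% names(a))
  if (triple) {
    need3 <- c(need2, "m3", "m13", "m23", "m123")
    missing3 <- setdiff(need3, names(a))
    if (length(missing3) > 0L) {
      abort(sprintf("missing mutant-cycle corner(s): %s",
                    paste(missing3, collapse = ", ")))
    }
  }
  if (any(a < 0)) abort("activities must be non-negative")
  if (a[["wt"]] <= 0) abort("wild-type activity must be positive")
  floor_val <- floor_frac * a[["wt"]]
  floored <- names(a)[a < floor_val]
  a[a < floor_val] <- floor_val
  if (triple) {
    ratio <- (a[["m123"]] * a[["m1"]] * a[["m2"]] * a[["m3"]]) /
      (a[["m12"]] * a[["m13"]] * a[["m23"]] * a[["wt"]])
    order <- 3L
  } else {
    ratio <- (a[["m12"]] * a[["wt"]]) / (a[["m1"]] * a[["m2"]])
    order <- 2L
  }
  verdict <- if (ratio >= rescue_threshold) "rescue"
  else if (ratio > independence_band) "interacting"
  else if (ratio >= 1 / independence_band) "independent"
  else "aggravating"
  tibble(order = order, ratio = unname(ratio), verdict = verdict,
         floored = paste(floored, collapse = ","))
}
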