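# Per-position conservation analysis of a selected pool: base-count
# profiles, Shannon information content (the quantity a sequence logo
# draws), consensus/core calling, and doping-rate estimation.

#' Build a per-position base-count profile
#'
#' @param table A `sequence`/`count` tibble of uniform-length sequences.
#' @param weighting `"reads"` adds each sequence's read count to its base
#'   cells (abundance-weighted, the default after selection);
#'   `"unique"` adds 1 per distinct sequence.
#' @return A tibble with columns `position`, `A`, `C`, `G`, `T`; every row
#'   sums to the same total weight. The weighting is kept in the
#'   `weighting` attribute.
#' @export
build_profile <- function(table, weighting = c("reads", "unique")) {
  weighting <- match.arg(weighting)
  if (nrow(table) == 0L) abort("cannot profile an empty table")
  table_length(table)
  m <- encode_seqs(table$sequence)
  w <- if (weighting == "reads") as.numeric(table$count) else
    rep(1, nrow(table))
  counts <- vapply(1:4, function(b) colSums((m == b) * w),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)
  out <- as_tibble(as.data.frame(counts, col.names = the_bases))
  names(out) <- the_bases
  out <- mutate(out, position = seq_len(ncol(m)), .before = 1L)
  attr(out, "weighting") <- weighting
  out
}

profile_matrix <- function(profile) {
  as.matrix(profile[, the_bases])
}

#' Per-position information content in bits
#'
#' `IC(pos) = 2 - H(pos)` with H the Shannon entropy (bits) of the four-base
#' frequency vector; no small-sample correction is applied. This is the bar
#' height of a sequence logo.
#'
#' @param profile A profile from [build_profile()], or any data frame with
#'   `position` and `A`/`C`/`G`/`T` count columns.
#' @return A tibble with columns `position`, `ic`.
#' @export
information_content <- function(profile) {
  cm <- profile_matrix(profile)
  tot <- rowSums(cm)
  if (any(tot <= 0)) abort("profile rows must have positive total weight")
  p <- cm / tot
  plogp <- ifelse(p > 0, p * log2(p), 0)
  tibble(position = profile$position, ic = pmax(0, 2 + rowSums(plogp)))
}

#' Consensus sequence and conserved core
#'
#' The consensus takes the most frequent base per position (ties resolve in
#' A<C<G<T order and are flagged); the core is the set of positions with
#' information content at or above `ic_threshold`, reported as merged
#' 1-based ranges.
#'
#' @param profile A profile from [build_profile()].
#' @param ic_threshold Core cutoff in bits, in `(0, 2]`.
#' @return A list with `consensus` (string), `ties` (positions whose argmax
#'   was tied), `core_positions` (integer vector) and `core_ranges` (tibble
#'   `start`/`end`).
#' @export
consensus_and_core <- function(profile, ic_threshold = 1.0) {
  if (ic_threshold <= 0 || ic_threshold > 2) {
    abort("`ic_threshold` must be in (0, 2]")
  }
  cm <- profile_matrix(profile)
  best <- apply(cm, 1L, which.max)               # first max = A<C<G<T order
  n_max <- rowSums(cm == cm[cbind(seq_len(nrow(cm)), best)])
  ic <- information_content(profile)$ic
  core <- profile$position[ic >= ic_threshold]
  list(consensus = paste(the_bases[best], collapse = ""),
       ties = profile$position[n_max > 1L],
       core_positions = core,
       core_ranges = positions_to_ranges(core))
}

# merge sorted 1-based positions into closed ranges
positions_to_ranges <- function(pos) {
  if (length(pos) == 0L) return(tibble(start = integer(), end = integer()))
  pos <- sort(unique(as.integer(pos)))
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  tibble(start = pos[head(brk, -1L) + 1L], end = pos[brk[-1L]])
}

#' Estimate the per-position doping rate of a pool
#'
#' Mean over positions of (1 - frequency of the reference base), with a
#' standard error from the per-position spread. Unbiased on unselected
#' pools; after selection, conserved positions pull the estimate down.
#'
#' @param profile A profile from [build_profile()].
#' @param reference Reference sequence (profile length).
#' @return A one-row tibble with `estimate`, `se` and `n_positions`.
#' @export
estimate_doping_rate <- function(profile, reference) {
  assert_scalar_string(reference, "reference")
  cm <- profile_matrix(profile)
  if (nchar(reference) != nrow(cm)) {
    abort("reference length does not match the profile")
  }
  refi <- match(strsplit(toupper(reference), "", fixed = TRUE)[[1]], the_bases)
  tot <- rowSums(cm)
  ref_freq <- cm[cbind(seq_len(nrow(cm)), refi)] / tot
  dev <- 1 - ref_freq
  tibble(estimate = mean(dev),
         se = stats::sd(dev) / sqrt(length(dev)),
         n_positions = length(dev))
}

#' Export a profile with IC and consensus as a logo-ready table
#'
#' @param profile A profile from [build_profile()].
#' @return A tibble with `position`, per-base frequencies, `ic` and
#'   `consensus`, suitable for TSV export and standard logo plotters.
#' @export
profile_summary <- function(profile) {
  cm <- profile_matrix(profile)
  freq <- cm / rowSums(cm)
  cons <- consensus_and_core(profile, ic_threshold = 2)  # threshold irrelevant
  out <- as_tibble(as.data.frame(freq))
  names(out) <- the_bases
  mutate(out,
         position = profile$position,
         ic = information_content(profile)$ic,
         consensus = strsplit(cons$consensus, "", fixed = TRUE)[[1]],
         .before = 1L)
}
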