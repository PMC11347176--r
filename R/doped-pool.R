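# Generative model of a doped selection experiment: partially mutagenized
# pools, a structure/conservation-based fitness, Bernoulli survival per
# molecule and multinomial resampling between rounds. This is the synthetic
# counterpart of a reselection experiment starting from a single isolate.

#' Doping model for a partially randomized library
#'
#' Describes chemical synthesis of a doped pool: each position of `reference`
#' is replaced, independently with probability `rate`, by one of the three
#' non-reference bases drawn from `alt_dist`. A rate of 0.21 with a uniform
#' alternative distribution reproduces the usual 21%-per-position doping used
#' in reselection libraries.
#'
#' @param reference Reference sequence (A/C/G/T string).
#' @param rate Per-position substitution probability in `[0, 1]`.
#' @param alt_dist Probabilities of the three alternative bases, summing to 1.
#'   Order is the non-reference bases in A<C<G<T order at each position.
#' @return An object of class `doping_model`.
#' @export
doping_model <- function(reference, rate = 0.21, alt_dist = rep(1 / 3, 3)) {
  assert_scalar_string(reference, "reference")
  reference <- toupper(reference)
  if (!grepl("^[ACGT]+$", reference)) {
    abort("`reference` may contain only A/C/G/T")
  }
  if (rate < 0 || rate > 1) abort("`rate` must be in [0, 1]")
  if (length(alt_dist) != 3L || any(alt_dist < 0) ||
      abs(sum(alt_dist) - 1) > 1e-8) {
    abort("`alt_dist` must be three non-negative probabilities summing to 1")
  }
  structure(list(reference = reference, rate = rate, alt_dist = alt_dist),
            class = "doping_model")
}

#' @export
print.doping_model <- function(x, ...) {
  cat(sprintf("<doping_model> %d nt, %.1f%% per-position doping\n",
              nchar(x$reference), 100 * x$rate))
  invisible(x)
}

# per-position base probability matrix (L x 4) implied by a doping model
doping_probs <- function(model) {
  ref <- strsplit(model$reference, "", fixed = TRUE)[[1]]
  L <- length(ref)
  p <- matrix(0, L, 4L, dimnames = list(NULL, the_bases))
  for (i in seq_len(L)) {
    r <- match(ref[[i]], the_bases)
    p[i, r] <- 1 - model$rate
    p[i, -r] <- model$rate * model$alt_dist
  }
  p
}

#' Sample a doped pool
#'
#' Draws `n` i.i.d. molecules from a [doping_model()] and tallies them into a
#' unique-sequence table.
#'
#' @param model A [doping_model()].
#' @param n Number of molecules.
#' @param seed Integer seed; the draw is reproducible.
#' @return A `sequence`/`count` tibble.
#' @export
sample_pool <- function(model, n, seed = 1L) {
  if (n < 1) abort("`n` must be >= 1")
  seqs <- sample_pool_seqs(model, n, seed)
  cnt <- sort(table(seqs), decreasing = TRUE)
  tibble(sequence = names(cnt), count = as.integer(cnt))
}

# raw per-molecule sample (character vector of length n)
sample_pool_seqs <- function(model, n, seed = 1L) {
  set.seed(seed)
  ref <- strsplit(model$reference, "", fixed = TRUE)[[1]]
  L <- length(ref)
  refi <- match(ref, the_bases)
  m <- matrix(refi, nrow = n, ncol = L, byrow = TRUE)
  mut <- matrix(runif(n * L) < model$rate, n, L)
  if (any(mut)) {
    # alternative bases in A<C<G<T order among the three non-reference bases
    alt_idx <- sample(3L, sum(mut), replace = TRUE, prob = model$alt_dist)
    ref_at <- m[mut]
    alts <- matrix(c(2L, 3L, 4L,   # ref A -> C,G,T
                     1L, 3L, 4L,   # ref C -> A,G,T
                     1L, 2L, 4L,   # ref G -> A,C,T
                     1L, 2L, 3L),  # ref T -> A,C,G
                   nrow = 4L, byrow = TRUE)
    m[mut] <- alts[cbind(ref_at, alt_idx)]
  }
  decode_seqs(m)
}

#' Fitness model for selection simulations
#'
#' A variant is fully active (activity `active_level`) when it has at most
#' `core_tolerance` mismatches to the reference over `core_positions` and
#' every stem listed in `stems` can form at least the required number of
#' pairs; otherwise it has `background_level` activity. With
#' `graded = TRUE` activity is instead `active_level` times the fraction of
#' satisfied constraints (the core requirement and each stem counting once).
#'
#' @param core_positions Integer vector of 1-based conserved positions.
#' @param core_tolerance Mismatches tolerated over the core at full activity.
#' @param stems Named integer vector/list: minimum formable pairs per stem.
#' @param active_level,background_level Activities in `[0, 1]` with
#'   `background_level <= active_level`.
#' @param graded Use the graded (fraction-of-constraints) variant.
#' @return An object of class `fitness_model`.
#' @export
fitness_model <- function(core_positions = integer(), core_tolerance = 0L,
                          stems = list(), active_level = 1.0,
                          background_level = 0.01, graded = FALSE) {
  if (background_level > active_level) {
    abort("`background_level` must be <= `active_level`")
  }
  if (any(c(active_level, background_level) < 0) ||
      any(c(active_level, background_level) > 1)) {
    abort("activity levels must lie in [0, 1]")
  }
  structure(list(core_positions = as.integer(core_positions),
                 core_tolerance = as.integer(core_tolerance),
                 stems = stems, active_level = active_level,
                 background_level = background_level, graded = graded),
            class = "fitness_model")
}

#' Activity of variants under a fitness model
#'
#' @param seqs Character vector of variant sequences (reference length).
#' @param fitness A [fitness_model()].
#' @param structure A [structure_model()] providing the stems named in
#'   `fitness$stems`.
#' @param reference Reference sequence supplying the core consensus.
#' @return Numeric vector of activities in `[0, 1]`.
#' @export
variant_activity <- function(seqs, fitness, structure, reference) {
  L <- nchar(reference)
  if (any(nchar(seqs) != L)) {
    abort("variant length does not match the reference")
  }
  m <- encode_seqs(seqs)
  refi <- match(strsplit(toupper(reference), "", fixed = TRUE)[[1]], the_bases)
  checks <- matrix(TRUE, nrow = length(seqs), ncol = 0L)
  if (length(fitness$core_positions) > 0L) {
    mm <- rowSums(m[, fitness$core_positions, drop = FALSE] !=
                    matrix(refi[fitness$core_positions], nrow = length(seqs),
                           ncol = length(fitness$core_positions), byrow = TRUE))
    checks <- cbind(checks, mm <= fitness$core_tolerance)
  }
  for (stem_name in names(fitness$stems)) {
    k <- formable_count(m, structure, stem_name, allow_gu = TRUE)
    checks <- cbind(checks, k >= fitness$stems[[stem_name]])
  }
  if (ncol(checks) == 0L) {
    return(rep(fitness$active_level, length(seqs)))
  }
  if (fitness$graded) {
    pmax(fitness$background_level,
         fitness$active_level * rowMeans(checks))
  } else {
    ifelse(rowSums(checks) == ncol(checks), fitness$active_level,
           fitness$background_level)
  }
}

#' Simulate selection rounds on a doped pool
#'
#' Round `r + 1` is a multinomial sample of `pool_size` molecules from the
#' survivors of round `r`, where each molecule survives independently with
#' probability equal to its activity (stringency and incubation time are
#' absorbed into the activity scale). Amplification is unbiased and
#' error-free: doping dominates the variation. `reads_per_round` sequencing
#' reads are drawn from each post-selection pool.
#'
#' @param model A [doping_model()] generating round-0 molecules.
#' @param fitness A [fitness_model()].
#' @param structure A [structure_model()].
#' @param pool_size Molecules carried between rounds.
#' @param rounds Number of selection rounds.
#' @param reads_per_round Sequencing depth of each per-round table.
#' @param seed Integer seed.
#' @return A list with `tables` (one `sequence`/`count` tibble per round) and
#'   `summary`, a tibble with columns `round`, `survival`, `unique_sequences`,
#'   `total_reads`.
#' @export
run_selection <- function(model, fitness, structure, pool_size = 10000L,
                          rounds = 3L, reads_per_round = 10000L, seed = 1L) {
  if (pool_size < 1 || rounds < 1 || reads_per_round < 1) {
    abort("`pool_size`, `rounds` and `reads_per_round` must be positive")
  }
  pool <- sample_pool(model, pool_size, seed = seed)
  set.seed(seed + 1L)
  act <- variant_activity(pool$sequence, fitness, structure, model$reference)
  tables <- vector("list", rounds)
  summary_rows <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    surv <- rbinom(nrow(pool), pool$count, act)
    if (sum(surv) == 0L) {
      abort(sprintf("pool extinction: no molecule survived round %d", r),
            class = "dzkit_extinction")
    }
    survival <- sum(surv) / sum(pool$count)
    keep <- surv > 0L
    pool <- tibble(sequence = pool$sequence[keep], count = surv[keep])
    act <- act[keep]
    # unbiased amplification back to pool_size
    amp <- rmultinom(1L, pool_size, pool$count)[, 1L]
    keep2 <- amp > 0L
    pool <- tibble(sequence = pool$sequence[keep2], count = amp[keep2])
    act <- act[keep2]
    reads <- rmultinom(1L, reads_per_round, pool$count)[, 1L]
    tab <- tibble(sequence = pool$sequence[reads > 0L],
                  count = reads[reads > 0L])
    tab <- arrange(tab, desc(.data$count))
    tables[[r]] <- tab
    summary_rows[[r]] <- tibble(round = r, survival = survival,
                                unique_sequences = nrow(tab),
                                total_reads = sum(tab$count))
  }
  list(tables = tables, summary = bind_rows(summary_rows))
}

#' Length of the ligated selection construct
#'
#' Bookkeeping for the round protocol: an insert with a primer-binding site
#' is ligated to a tag, e.g. an 85-nt mutagenized region plus a 20-nt primer
#' site gives the 105-nt pool molecule, and ligation of a 20-nt tag gives the
#' 125-nt product recovered from the gel.
#'
#' @param insert_length,primer_site_length,tag_length Segment lengths (nt).
#' @return Total construct length (integer).
#' @export
#' @examples
#' ligated_length(85, 20, 20)  # 125
#' ligated_length(85, 20, 0)   # 105
ligated_length <- function(insert_length, primer_site_length = 0L,
                           tag_length = 0L) {
  lens <- c(insert_length, primer_site_length, tag_length)
  if (any(lens < 0)) abort("segment lengths must be >= 0")
  as.integer(sum(lens))
}
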