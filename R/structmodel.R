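# Secondary-structure bookkeeping: stems as typed position pairs, pairing
# potential of variants, an exact Poisson-binomial null for pairing under a
# doping model, and expected imino-proton signal counts (one per canonical
# pair, two per G-T/T-G wobble, which has two tautomeric forms).

#' Secondary structure model as typed, stem-grouped base pairs
#'
#' @param pairs A data frame with columns `i`, `j` (1-based, `i < j`), `type`
#'   (`"canonical"` or `"wobble"`) and `stem` (stem name).
#' @param length Sequence length the model applies to.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(pairs, length) {
  pairs <- as_tibble(pairs)
  needed <- c("i", "j", "type", "stem")
  if (!all(needed %in% names(pairs))) {
    abort("`pairs` needs columns i, j, type, stem")
  }
  pairs$i <- as.integer(pairs$i)
  pairs$j <- as.integer(pairs$j)
  if (nrow(pairs) > 0L) {
    if (any(pairs$i >= pairs$j)) abort("pairs must satisfy i < j")
    if (any(pairs$i < 1L) || any(pairs$j > length)) {
      abort("pair positions must lie within the sequence length")
    }
    pos <- c(pairs$i, pairs$j)
    if (anyDuplicated(pos)) abort("a position may belong to at most one pair")
    if (!all(pairs$type %in% c("canonical", "wobble"))) {
      abort("pair `type` must be 'canonical' or 'wobble'")
    }
  }
  structure(list(pairs = pairs, length = as.integer(length)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  comp <- table(x$pairs$type)
  cat(sprintf("<structure_model> %d nt, %d pairs (%d canonical, %d wobble), stems: %s\n",
              x$length, nrow(x$pairs),
              if ("canonical" %in% names(comp)) comp[["canonical"]] else 0L,
              if ("wobble" %in% names(comp)) comp[["wobble"]] else 0L,
              paste(unique(x$pairs$stem), collapse = ", ")))
  invisible(x)
}

#' Are two bases complementary?
#'
#' Watson-Crick pairs always count; G-T/T-G wobbles (the DNA counterpart of
#' G-U) count when `allow_gu` is set.
#'
#' @param a,b Bases in `A`, `C`, `G`, `T` (vectorized).
#' @param allow_gu Accept G-T/T-G wobble pairs.
#' @return Logical vector.
#' @export
pair_complementary <- function(a, b, allow_gu = TRUE) {
  a <- toupper(a)
  b <- toupper(b)
  if (!all(a %in% the_bases) || !all(b %in% the_bases)) {
    abort("bases must be one of A, C, G, T")
  }
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  if (allow_gu) {
    wc | (a == "G" & b == "T") | (a == "T" & b == "G")
  } else {
    wc
  }
}

stem_pairs <- function(model, stem) {
  p <- model$pairs[model$pairs$stem == stem, , drop = FALSE]
  if (nrow(p) == 0L && !(stem %in% model$pairs$stem)) {
    abort(sprintf("unknown stem: %s", stem))
  }
  p
}

# vectorized count of formable pairs for encoded sequences (n x L int matrix)
formable_count <- function(m, structure, stem, allow_gu = TRUE) {
  p <- stem_pairs(structure, stem)
  if (nrow(p) == 0L) return(rep(0L, nrow(m)))
  # complementarity lookup over encoded bases (A=1,C=2,G=3,T=4)
  comp <- matrix(FALSE, 4L, 4L)
  comp[cbind(c(1L, 4L, 3L, 2L), c(4L, 1L, 2L, 3L))] <- TRUE
  if (allow_gu) comp[cbind(c(3L, 4L), c(4L, 3L))] <- TRUE
  k <- rep(0L, nrow(m))
  for (r in seq_len(nrow(p))) {
    k <- k + comp[cbind(m[, p$i[[r]]], m[, p$j[[r]]])]
  }
  k
}

#' Pairing potential of a variant against one stem
#'
#' @param seq Variant sequence (length must equal the model length).
#' @param structure A [structure_model()].
#' @param stem Stem name.
#' @param allow_gu Accept G-T/T-G wobbles as formable.
#' @return A list with `formable` (k), `total` (n) and `per_pair`, a tibble
#'   of each pair with its bases and formability.
#' @export
formable_pairs <- function(seq, structure, stem, allow_gu = TRUE) {
  assert_scalar_string(seq, "seq")
  if (nchar(seq) != structure$length) {
    abort("sequence length does not match the structure model")
  }
  p <- stem_pairs(structure, stem)
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  ok <- pair_complementary(ch[p$i], ch[p$j], allow_gu = allow_gu)
  list(formable = sum(ok), total = nrow(p),
       per_pair = tibble(i = p$i, j = p$j, base_i = ch[p$i], base_j = ch[p$j],
                         type = p$type, formable = ok))
}

#' Pairing-potential statistics of abundant variants
#'
#' For every variant with a read count of at least `read_floor`, counts how
#' many pairs of `stem` it can form; reports the minimum, the histogram of k
#' and the qualifying variants. Used to ask whether all abundant variants
#' retain a stem (e.g. at least seven of eight pairs).
#'
#' @param table A `sequence`/`count` table.
#' @param structure A [structure_model()].
#' @param stem Stem name.
#' @param read_floor Minimum read count for a variant to qualify.
#' @param allow_gu Accept G-T/T-G wobbles.
#' @return A list with `min_k`, `histogram` (tibble `k`/`n_variants`), and
#'   `variants` (tibble `sequence`/`count`/`k`). With no qualifying variant,
#'   `min_k` is `NA` and the tibbles are empty.
#' @export
stem_statistic <- function(table, structure, stem, read_floor = 1L,
                           allow_gu = TRUE) {
  table_length(table)  # uniform-length check
  qual <- table[table$count >= read_floor, , drop = FALSE]
  if (nrow(qual) == 0L) {
    return(list(min_k = NA_integer_,
                histogram = tibble(k = integer(), n_variants = integer()),
                variants = tibble(sequence = character(), count = integer(),
                                  k = integer())))
  }
  k <- formable_count(encode_seqs(qual$sequence), structure, stem,
                      allow_gu = allow_gu)
  hist <- count(tibble(k = k), .data$k, name = "n_variants")
  list(min_k = min(k), histogram = hist,
       variants = tibble(sequence = qual$sequence, count = qual$count, k = k))
}

#' Exact pairing-count null under a doping model
#'
#' For each pair of `stem` the complementarity probability of a doped variant
#' is obtained by enumerating all 16 dinucleotide outcomes at the two
#' positions; the number of formable pairs k is then Poisson-binomial over
#' the per-pair probabilities, convolved exactly.
#'
#' @param model A [doping_model()] (its reference must span the stem).
#' @param structure A [structure_model()].
#' @param stem Stem name.
#' @param allow_gu Accept G-T/T-G wobbles.
#' @return A list with `per_pair_prob` (numeric vector), and `distribution`,
#'   a tibble with columns `k`, `prob` and `tail` (`tail[k] = P(K >= k)`).
#' @export
null_pairing_distribution <- function(model, structure, stem,
                                      allow_gu = TRUE) {
  p <- stem_pairs(structure, stem)
  if (nrow(p) > 0L && max(p$j) > nchar(model$reference)) {
    abort("stem pairs fall outside the doping-model reference")
  }
  probs <- doping_probs(model)
  comp <- outer(the_bases, the_bases,
                function(a, b) pair_complementary(a, b, allow_gu = allow_gu))
  per_pair <- vapply(seq_len(nrow(p)), function(r) {
    sum(outer(probs[p$i[[r]], ], probs[p$j[[r]], ]) * comp)
  }, numeric(1))
  # exact Poisson-binomial mass by sequential convolution
  mass <- 1
  for (q in per_pair) {
    mass <- c(mass * (1 - q), 0) + c(0, mass * q)
  }
  k <- seq_along(mass) - 1L
  list(per_pair_prob = per_pair,
       distribution = tibble(k = k, prob = mass,
                             tail = rev(cumsum(rev(mass)))))
}

#' Expected number of distinct imino-proton signals
#'
#' Each canonical base pair contributes one imino signal in the 12-15 ppm
#' window; each G-T/T-G wobble contributes two (one per tautomer).
#'
#' @param structure A [structure_model()].
#' @return Integer signal count.
#' @export
#' @examples
#' expected_imino_signals(apollon_structure())  # 12 + 2*4 = 20
expected_imino_signals <- function(structure) {
  sum(ifelse(structure$pairs$type == "wobble", 2L, 1L))
}

#' Remove a stem from a structure model
#'
#' @param structure A [structure_model()].
#' @param stem Name of the stem to drop.
#' @return A new `structure_model` without that stem's pairs.
#' @export
delete_stem <- function(structure, stem) {
  if (!(stem %in% structure$pairs$stem)) {
    abort(sprintf("unknown stem: %s", stem))
  }
  structure_model(structure$pairs[structure$pairs$stem != stem, , drop = FALSE],
                  structure$length)
}

#' Serialize a structure model
#'
#' `as_dot_bracket()` gives the pairs-only dot-bracket view plus an
#' annotation line marking wobble pairs with `w`; `write_structure()` /
#' `read_structure()` round-trip the full typed, stem-grouped model as TSV.
#'
#' @param structure A [structure_model()].
#' @return A two-element character vector (structure line, annotation line).
#' @export
as_dot_bracket <- function(structure) {
  db <- rep(".", structure$length)
  ann <- rep(".", structure$length)
  db[structure$pairs$i] <- "("
  db[structure$pairs$j] <- ")"
  w <- structure$pairs$type == "wobble"
  ann[structure$pairs$i[w]] <- "w"
  ann[structure$pairs$j[w]] <- "w"
  c(paste(db, collapse = ""), paste(ann, collapse = ""))
}

#' @rdname as_dot_bracket
#' @param path File path.
#' @export
write_structure <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# structure_model length=%d", structure$length), con)
  writeLines("i\tj\ttype\tstem", con)
  writeLines(with(structure$pairs, paste(i, j, type, stem, sep = "\t")), con)
  invisible(path)
}

#' @rdname as_dot_bracket
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# structure_model")]
  if (length(hdr) != 1L) abort(sprintf("not a structure model file: %s", path))
  len <- as.integer(sub(".*length=", "", hdr))
  body <- lines[!startsWith(lines, "#")]
  if (body[[1L]] != "i\tj\ttype\tstem") abort("malformed structure header row")
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  pairs <- tibble(i = as.integer(purrr::map_chr(rows, 1L)),
                  j = as.integer(purrr::map_chr(rows, 2L)),
                  type = purrr::map_chr(rows, 3L),
                  stem = purrr::map_chr(rows, 4L))
  structure_model(pairs, len)
}
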