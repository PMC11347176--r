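# Desk-scale read processing: FASTA/FASTQ I/O, orientation + primer clipping,
# pair merging, length filtering and unique-sequence counting. This mirrors the
# standard amplicon pipeline (adapter trimming, merging, orientation unifying,
# primer clipping, length filter, unique counting) as small composable
# functions over tibbles of reads.

#' Read a FASTQ file into a tibble of reads
#'
#' Strict 4-line-record FASTQ parser (gzip accepted). Qualities are kept as
#' their Phred+33 character string; see [phred_scores()] to decode.
#'
#' @param path Path to a FASTQ file, optionally gz-compressed.
#' @return A tibble with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(tibble(id = character(), sequence = character(),
                  quality = character()))
  }
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("truncated FASTQ record starting at line %d",
                  4L * (length(lines) %/% 4L) + 1L))
  }
  idx <- seq(1L, length(lines), by = 4L)
  ids <- lines[idx]
  seqs <- lines[idx + 1L]
  seps <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  bad_id <- which(!startsWith(ids, "@"))
  if (length(bad_id) > 0L) {
    abort(sprintf("malformed FASTQ header at line %d (expected '@')",
                  idx[bad_id[[1L]]]))
  }
  bad_sep <- which(!startsWith(seps, "+"))
  if (length(bad_sep) > 0L) {
    abort(sprintf("missing '+' separator at line %d", idx[bad_sep[[1L]]] + 2L))
  }
  bad_len <- which(nchar(seqs) != nchar(quals))
  if (length(bad_len) > 0L) {
    abort(sprintf("quality length differs from sequence length at line %d",
                  idx[bad_len[[1L]]] + 3L))
  }
  tibble(id = sub("^@", "", ids), sequence = toupper(seqs), quality = quals)
}

#' Read a FASTA file into a tibble
#'
#' @param path Path to a FASTA file, optionally gz-compressed.
#' @return A tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nchar(lines) > 0L]
  if (length(lines) == 0L) {
    return(tibble(id = character(), sequence = character()))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[[1L]]) abort("FASTA must start with a '>' header at line 1")
  grp <- cumsum(is_hdr)
  ids <- sub("^>", "", lines[is_hdr])
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 paste, character(1), collapse = "")
  # headers with no sequence line yield empty strings
  out <- setNames(rep("", length(ids)), as.character(seq_along(ids)))
  out[names(seqs)] <- seqs
  tibble(id = ids, sequence = toupper(unname(out)))
}

#' Write reads to FASTA / FASTQ
#'
#' @param reads A data frame with columns `id`, `sequence` (and `quality` for
#'   FASTQ).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  writeLines(rbind(paste0(">", reads$id), reads$sequence), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(reads, path) {
  if (!("quality" %in% names(reads))) {
    abort("write_fastq() needs a `quality` column")
  }
  writeLines(rbind(paste0("@", reads$id), reads$sequence, "+", reads$quality),
             path)
  invisible(path)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param quality Character vector of Phred+33 encoded quality strings.
#' @return A list of integer vectors.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Unify read orientation and clip primers
#'
#' Looks for the forward primer (within `max_mismatch` substitutions) at the
#' 5' end of each read or of its reverse complement, requires the reverse
#' complement of the reverse primer at the 3' end, and returns the insert in
#' forward orientation. Substitution-only (Hamming) matching: indel-containing
#' primer sites are rejected by construction.
#'
#' @param reads A data frame of reads (`id`, `sequence`, optional `quality`).
#' @param fwd_primer,rev_primer Primer sequences, 5'->3' on their own strands.
#' @param max_mismatch Maximum substitutions tolerated in each primer match.
#' @return A tibble with columns `id`, `sequence` (the clipped insert, `NA`
#'   when rejected), `quality` (if supplied), `orientation`, and `status`
#'   (`"ok"` or a rejection reason).
#' @export
clip_and_orient <- function(reads, fwd_primer, rev_primer, max_mismatch = 2) {
  assert_scalar_string(fwd_primer, "fwd_primer")
  assert_scalar_string(rev_primer, "rev_primer")
  if (max_mismatch < 0) abort("`max_mismatch` must be >= 0")
  fwd <- toupper(fwd_primer)
  rev3 <- revcomp(toupper(rev_primer))
  nf <- nchar(fwd)
  nr <- nchar(rev3)
  has_q <- "quality" %in% names(reads)

  one <- function(seq, qual) {
    n <- nchar(seq)
    if (n < nf + nr) {
      return(list(sequence = NA_character_, quality = NA_character_,
                  orientation = NA_character_,
                  status = "primer_longer_than_read"))
    }
    for (orient in c("forward", "reverse")) {
      s <- if (orient == "forward") seq else revcomp(seq)
      q <- if (orient == "forward" || !has_q || is.na(qual)) qual else {
        paste(rev(strsplit(qual, "", fixed = TRUE)[[1]]), collapse = "")
      }
      if (hamming(substr(s, 1L, nf), fwd) <= max_mismatch) {
        if (hamming(substr(s, n - nr + 1L, n), rev3) > max_mismatch) {
          return(list(sequence = NA_character_, quality = NA_character_,
                      orientation = orient, status = "no_rev_primer"))
        }
        ins <- substr(s, nf + 1L, n - nr)
        insq <- if (has_q && !is.na(q)) substr(q, nf + 1L, n - nr) else NA_character_
        return(list(sequence = ins, quality = insq, orientation = orient,
                    status = "ok"))
      }
    }
    list(sequence = NA_character_, quality = NA_character_,
         orientation = NA_character_, status = "no_fwd_primer")
  }

  quals <- if (has_q) reads[["quality"]] else rep(NA_character_, nrow(reads))
  res <- purrr::map2(reads$sequence, quals, one)
  out <- tibble(
    id = reads$id,
    sequence = purrr::map_chr(res, "sequence"),
    quality = purrr::map_chr(res, "quality"),
    orientation = purrr::map_chr(res, "orientation"),
    status = purrr::map_chr(res, "status")
  )
  if (!has_q) out$quality <- NULL
  out
}

#' Merge a read pair by 3' overlap
#'
#' Finds the longest suffix of `r1` that matches a prefix of the reverse
#' complement of `r2` with at least `min_overlap` bases and a mismatch
#' fraction at most `max_mismatch_frac`; ties between equally long overlaps
#' cannot arise (lengths are scanned from longest down). At disagreeing
#' positions the base with the higher Phred score wins (r1 wins ties).
#'
#' @param r1,r2 Single reads as one-row data frames or lists with `sequence`
#'   and optional `quality`.
#' @param min_overlap Minimum acceptable overlap length (>= 1).
#' @param max_mismatch_frac Maximum fraction of mismatches in the overlap.
#' @return A one-row tibble with `sequence`, `quality`, `overlap`,
#'   `mismatches` and `status` (`"ok"` or `"no_overlap"`).
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10, max_mismatch_frac = 0.1) {
  if (min_overlap < 1) abort("`min_overlap` must be >= 1")
  s1 <- toupper(r1$sequence[[1]])
  s2 <- revcomp(toupper(r2$sequence[[1]]))
  q1 <- if ("quality" %in% names(r1)) phred_scores(r1[["quality"]][[1]])[[1]] else
    rep(30L, nchar(s1))
  q2raw <- if ("quality" %in% names(r2)) phred_scores(r2[["quality"]][[1]])[[1]] else
    rep(30L, nchar(s2))
  q2 <- rev(q2raw)  # align with the reverse-complemented sequence
  c1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  n1 <- length(c1)
  n2 <- length(c2)

  if (min(n1, n2) < min_overlap) {
    return(tibble(sequence = NA_character_, quality = NA_character_,
                  overlap = NA_integer_, mismatches = NA_integer_,
                  status = "no_overlap"))
  }
  for (ov in seq(min(n1, n2), min_overlap, by = -1L)) {
    a <- c1[(n1 - ov + 1L):n1]
    b <- c2[1L:ov]
    mm <- sum(a != b)
    if (mm / ov <= max_mismatch_frac) {
      qa <- q1[(n1 - ov + 1L):n1]
      qb <- q2[1L:ov]
      cons <- ifelse(a == b | qa >= qb, a, b)
      qcons <- pmax(qa, qb)
      merged <- paste(c(head(c1, n1 - ov), cons, tail(c2, n2 - ov)),
                      collapse = "")
      mq <- c(head(q1, n1 - ov), qcons, tail(q2, n2 - ov))
      return(tibble(sequence = merged,
                    quality = paste(rawToChar(as.raw(mq + 33L), multiple = TRUE),
                                    collapse = ""),
                    overlap = ov, mismatches = mm, status = "ok"))
    }
  }
  tibble(sequence = NA_character_, quality = NA_character_,
         overlap = NA_integer_, mismatches = NA_integer_,
         status = "no_overlap")
}

#' Length-filter reads and count unique sequences
#'
#' Drops reads containing `N` or with length outside `[length_min,
#' length_max]`, then keeps only the modal surviving length (positional
#' analyses need one uniform length; doped synthesis produces
#' substitution-only variants, so off-length reads are treated as
#' indel artefacts). Ties in the mode resolve to the shorter length.
#'
#' @param reads A data frame with a `sequence` column, or a character vector.
#' @param length_min,length_max Inclusive length window.
#' @return A `sequence`/`count` tibble sorted by decreasing count, with
#'   attributes `total_reads`, `seq_length` and `n_rejected`.
#' @export
filter_and_count <- function(reads, length_min = 1L, length_max = Inf) {
  if (length_min > length_max) abort("`length_min` must be <= `length_max`")
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  n_in <- length(seqs)
  seqs <- toupper(seqs)
  len <- nchar(seqs)
  keep <- !grepl("N", seqs, fixed = TRUE) & len >= length_min & len <= length_max
  seqs <- seqs[keep]
  if (length(seqs) == 0L) {
    warn("all reads were filtered out; returning an empty table")
    out <- tibble(sequence = character(), count = integer())
    attr(out, "total_reads") <- 0L
    attr(out, "seq_length") <- NA_integer_
    attr(out, "n_rejected") <- n_in
    return(out)
  }
  lt <- table(nchar(seqs))
  modal <- min(as.integer(names(lt)[lt == max(lt)]))
  seqs <- seqs[nchar(seqs) == modal]
  cnt <- sort(table(seqs), decreasing = TRUE)
  out <- tibble(sequence = names(cnt), count = as.integer(cnt))
  attr(out, "total_reads") <- sum(out$count)
  attr(out, "seq_length") <- modal
  attr(out, "n_rejected") <- n_in - sum(out$count)
  out
}

#' Serialize / read a unique-sequence table
#'
#' Two-column TSV (`sequence`, `count`) with a one-line header; `#` lines are
#' treated as provenance comments and skipped on read.
#'
#' @param table A `sequence`/`count` data frame.
#' @param path File path.
#' @param comments Optional character vector written as leading `#` lines.
#' @return `path` (write) or a tibble (read).
#' @export
write_seq_table <- function(table, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments) > 0L) writeLines(paste0("# ", comments), con)
  writeLines("sequence\tcount", con)
  writeLines(paste(table$sequence, table$count, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_seq_table
#' @export
read_seq_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L || lines[[1L]] != "sequence\tcount") {
    abort(sprintf("not a sequence-count table: %s", path))
  }
  body <- lines[-1L]
  if (length(body) == 0L) return(tibble(sequence = character(), count = integer()))
  parts <- strsplit(body, "\t", fixed = TRUE)
  out <- tibble(sequence = purrr::map_chr(parts, 1L),
                count = as.integer(purrr::map_chr(parts, 2L)))
  attr(out, "total_reads") <- sum(out$count)
  attr(out, "seq_length") <- nchar(out$sequence[[1L]])
  out
}

# total reads in a sequence/count table
table_total <- function(table) sum(table$count)

# uniform sequence length of a table (errors if mixed)
table_length <- function(table) {
  lens <- unique(nchar(table$sequence))
  if (length(lens) > 1L) abort("table sequences are not a uniform length")
  lens
}
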