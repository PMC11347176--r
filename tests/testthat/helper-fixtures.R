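# Shared fixtures and independent oracles.

# 20-nt toy reference with one planted 4-pair stem (3..6 paired to 18..15).
toy_stem_setup <- function() {
  chars <- strsplit("ACGTACGTACGTACGTACGT", "", fixed = TRUE)[[1]]
  pairs <- tibble::tibble(i = 3:6, j = 18:15, type = "canonical", stem = "S1")
  for (r in seq_len(nrow(pairs))) {
    chars[pairs$j[r]] <- chartr("ACGT", "TGCA", chars[pairs$i[r]])
  }
  ref <- paste(chars, collapse = "")
  list(ref = ref,
       structure = structure_model(pairs, 20L),
       model = doping_model(ref, 0.21),
       fitness = fitness_model(stems = list(S1 = 4L), active_level = 1,
                               background_level = 0.01))
}

# Independent enumeration oracle: probability that a doped variant keeps a
# complementary pair at two positions with reference bases `ra`, `rb`.
# Deliberately does not reuse pair_complementary() or doping_probs().
oracle_pair_prob <- function(ra, rb, d, allow_gu = TRUE) {
  bases <- c("A", "C", "G", "T")
  comp_set <- c("AT", "TA", "GC", "CG")
  if (allow_gu) comp_set <- c(comp_set, "GT", "TG")
  pr <- function(ref, b) if (b == ref) 1 - d else d / 3
  total <- 0
  for (a in bases) for (b in bases) {
    if (paste0(a, b) %in% comp_set) total <- total + pr(ra, a) * pr(rb, b)
  }
  total
}

# single substitution at 1-based position `pos`
substitute_base <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}
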