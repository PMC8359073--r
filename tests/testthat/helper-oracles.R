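# Independent brute-force oracles and small construction helpers shared by
# the suites. Oracles deliberately avoid the package's own code paths.

# covered-position count by direct enumeration
brute_force_union_size <- function(starts, stops) {
  if (length(starts) == 0L) return(0L)
  length(unique(unlist(mapply(seq, starts, stops, SIMPLIFY = FALSE))))
}

# single-linkage clusters as the transitive closure of identity >= threshold
brute_force_single_linkage <- function(identity, threshold) {
  n <- nrow(identity)
  adj <- identity >= threshold
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  # canonical membership: smallest reachable index
  apply(reach, 1L, function(r) min(which(r)))
}

random_identity_matrix <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  dimnames(m) <- list(sprintf("s%02d", seq_len(n)), sprintf("s%02d", seq_len(n)))
  m
}

# one clean sequence with a single full-coverage plus-strand hit pair
good_seq_inputs <- function(id = "s1", len = 1000, model = "SSU_bac",
                            score = 900, seq_stop = len) {
  seqs <- as_seq_records(id, strrep("A", len))
  s1 <- data.frame(seq_id = id, model_name = model, model_start = 1,
                   model_stop = min(len, 1533), seq_start = 1,
                   seq_stop = seq_stop, strand = "plus", bit_score = score,
                   e_value = 1e-90, stage = 1L, stringsAsFactors = FALSE)
  s2 <- s1
  s2$stage <- 2L
  list(seqs = seqs, stage1 = s1, stage2 = s2, models = fixture_models())
}

run_features <- function(inp, opts = typer_opts()) {
  res <- profile_validate(inp$seqs, inp$stage1, inp$stage2, inp$models, opts)
  strsplit(res$features, ";", fixed = TRUE)[[1]]
}
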