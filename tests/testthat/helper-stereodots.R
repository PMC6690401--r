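# Shared fixture builders. All stimuli are generated in code at test time.

# an ensemble of normalized pairs; same-polarity conditions are converted
# from the mixed pattern so conditions share dot patterns
make_ensemble <- function(params, n, seed, polarity = "mixed") {
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- derive_seed(seed, i)
    raw <- generate_pair(p)
    if (polarity %in% c("white", "black")) raw <- to_same_polarity(raw, polarity)
    normalize_pair(raw)
  })
}

# raw (unnormalized) mixed pairs, for provenance-based statistics
make_raw_ensemble <- function(params, n, seed) {
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- derive_seed(seed, i)
    generate_pair(p)
  })
}

# mean and standard error of a statistic applied to each member of a raw
# ensemble
ensemble_stat <- function(raws, f) {
  v <- vapply(raws, f, numeric(1))
  c(mean = mean(v), se = sd(v) / sqrt(length(v)))
}
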