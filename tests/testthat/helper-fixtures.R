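# shared in-code fixtures

random_table <- function(n = 8, feats = c("shape_Volume", "shape_Flatness",
                                          "glcm_SumEntropy", "glrlm_RunVariance"),
                         labeled = TRUE, seed = 42) {
    set.seed(seed)
    m <- matrix(rnorm(n * length(feats)), n,
                dimnames = list(sprintf("s%02d", seq_len(n)), feats))
    lab <- if (labeled) rep_len(c(0L, 1L), n) else NULL
    RadiomicsExperiment(m, labels = lab)
}

# two well-separated sample blobs: features equal within blobs are smooth
# on any reasonable neighborhood graph
two_blob_matrix <- function(n_per = 10, seed = 3) {
    set.seed(seed)
    blob <- rep(c(0, 10), each = n_per)
    smooth <- blob + rnorm(2 * n_per, 0, 0.1)
    noise <- rnorm(2 * n_per)
    anchor1 <- blob + rnorm(2 * n_per, 0, 0.3)
    anchor2 <- blob + rnorm(2 * n_per, 0, 0.3)
    m <- cbind(anchor1 = anchor1, anchor2 = anchor2,
               smooth = smooth, noise = noise)
    rownames(m) <- sprintf("b%02d", seq_len(2 * n_per))
    m
}
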