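# Shared fixture builders: everything is generated in code at test time.

make_em <- function(values, genes, samples, platform = "test") {
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, platform)
}

# A tiny deterministic 3 x 2 matrix
tiny_em <- function() {
  make_em(matrix(c(5, 6, 7, 8, 9, 10), nrow = 3, byrow = TRUE),
          genes = c("CD19", "BTK", "GENE1"), samples = c("s1", "s2"))
}

# One dose-response series on the canonical 9-dose twofold ladder
series_df <- function(viability, sample_id = "CL1", top_dose = 2) {
  d <- dose_ladder(9, top_dose)
  data.frame(sample_id = sample_id, drug_id = "drugA", dose_uM = d,
             viability = viability, stringsAsFactors = FALSE)
}

# Exhaustive-enumeration oracle for the two-sided Mann-Whitney p:
# all C(na+nb, na) assignments of the pooled values, tail defined by
# distance of U from its null mean.
mw_enum_oracle <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * length(b) / 2
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(idx) sum(rk[idx]) - na * (na + 1) / 2)
  list(u = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
}

planted_genes <- c("CD19", "EBF1", "PAX5", "BTK", "BLNK")

# A small deterministic training setup for classifier tests: responders sit
# high on all five model genes, non-responders low; all RAs land at 6.
fit_demo_model <- function() {
  genes <- c("CD19", "EBF1", "PAX5", "BTK", "BLNK", "GENE1")
  resp <- outer(rep(8, 6), rep(1, 3)) + 0.1 * seq_len(6)
  nonr <- outer(rep(4, 6), rep(1, 3)) - 0.1 * seq_len(6)
  em <- make_em(cbind(resp, nonr), genes, sprintf("s%d", 1:6))
  calls <- data.frame(sample_id = sprintf("s%d", 1:6),
                      response_class = rep(c("RESPONDER", "NON_RESPONDER"), each = 3),
                      stringsAsFactors = FALSE)
  fit_ra_model(em, calls, "CD19", c("EBF1", "PAX5", "BTK", "BLNK"))
}
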