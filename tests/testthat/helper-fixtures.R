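# Shared fixtures: small genotype tables and frequency panels built in code.

# a fixed two-locus frequency panel (population frequencies, no correction)
fixtureFreqs <- function() {
  alleleFreqTable(list(L1 = c(`10` = 0.5, `11` = 0.5),
                       L2 = c(`20` = 0.25, `21` = 0.25, `22` = 0.5)),
                  referenceSet = "fixture")
}

# three-individual table used by the I/O round-trip tests
fixtureTable <- function() {
  a1 <- matrix(c(10L, 10L, NA, 20L, 21L, 20L), 3, 2,
               dimnames = list(NULL, c("L1", "L2")))
  a2 <- matrix(c(11L, 10L, NA, 22L, 21L, 20L), 3, 2,
               dimnames = list(NULL, c("L1", "L2")))
  GenotypeTable(a1, a2,
                data.frame(id = c("F1", "M1", "J1"),
                           sex = c("female", "male", "unknown"),
                           age_class = c("adult", "adult", "immature"),
                           role = c("adult_female", "silverback",
                                    "immature"),
                           group = c("G1", "G1", "G2"),
                           country = c("X", "X", "Y")))
}

# HWE table of n unrelated individuals at the default simulated panel
fixtureUnrelated <- function(n, freqs, ids = sprintf("I%d", seq_len(n))) {
  g <- gorillakin:::.simHweGenotypes(freqs, n)
  rownames(g$a1) <- rownames(g$a2) <- ids
  GenotypeTable(g$a1, g$a2, data.frame(id = ids))
}

defaultFreqs <- function(seed = 1234)
  founderFrequencies(simulationConfig(), seed = seed)
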