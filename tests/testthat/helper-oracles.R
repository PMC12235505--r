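# Independent oracles, kept deliberately naive and separate from the package
# implementation paths they check.

# element masses entered directly (not read from the package table)
.ORACLE_EL <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                O = 15.9949146196, Na = 22.9897692809)
.ORACLE_E <- 0.000548579909

oracle_mass <- function(counts) {
  sum(.ORACLE_EL[names(counts)] * counts)
}

# monomer masses from element counts
.ORACLE_MONOMERS <- list(
  AA = c(C = 6, H = 10, O = 4),
  TA = c(C = 8, H = 6, O = 4),
  SeA = c(C = 10, H = 18, O = 4),
  BD = c(C = 4, H = 10, O = 2),
  LA = c(C = 3, H = 6, O = 3)
)
.ORACLE_WATER <- oracle_mass(c(H = 2, O = 1))

# naive monomer-by-monomer summation: every diacid-diol unit is
# diacid + butanediol - 2 waters, every lactate unit is lactic acid - 1 water,
# plus the end-group mass (nothing for rings)
oracle_species_mass <- function(n_aa_bd, n_ta_bd, n_sea_bd, n_la,
                                end_group = "none") {
  unit_mass <- function(diacid) {
    oracle_mass(.ORACLE_MONOMERS[[diacid]]) +
      oracle_mass(.ORACLE_MONOMERS$BD) - 2 * .ORACLE_WATER
  }
  total <- n_aa_bd * unit_mass("AA") + n_ta_bd * unit_mass("TA") +
    n_sea_bd * unit_mass("SeA") +
    n_la * (oracle_mass(.ORACLE_MONOMERS$LA) - .ORACLE_WATER)
  total + switch(end_group,
                 none = 0,
                 free = .ORACLE_WATER,
                 methyl = oracle_mass(c(C = 1, H = 4, O = 1)),
                 bd = oracle_mass(.ORACLE_MONOMERS$BD))
}

# closed-form multiset coefficient: compositions of t units over k families
multiset_count <- function(t, k) choose(t + k - 1, k - 1)

# random valid formula string over CHNO for property tests
random_formula <- function() {
  n <- c(C = sample(0:30, 1), H = sample(0:60, 1),
         N = sample(0:3, 1), O = sample(0:20, 1))
  n <- n[n > 0]
  if (length(n) == 0) n <- c(C = 1)
  paste0(names(n), n, collapse = "")
}
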