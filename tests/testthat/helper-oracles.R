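# Independent oracles used across the suite.

# Free-ligand concentration by root-finding on the single-site mass balance,
# independent of the closed-form quadratic in the package.
oracle_free_ligand <- function(site_total, ligand_total, kd) {
  if (ligand_total == 0) return(0)
  f <- function(x) x + site_total * x / (kd + x) - ligand_total
  stats::uniroot(f, c(0, ligand_total), tol = 1e-15 * max(1, ligand_total),
                 maxiter = 2000)$root
}

# Michaelis-Menten rate, written out for readability in expectations
oracle_mm <- function(conc, vmax, km) vmax * conc / (km + conc)

# default acceptor constants used throughout (free-NADH Michaelis pair)
acceptor_mm_default <- function() michaelis_params(140, 4.4)

make_null_dataset <- function(v_true, sites, noise_sd = 0.02) {
  gen_buffering_dataset(donor_rate_constants("tight", channeling = FALSE),
                        "titrate_gapdh_fixed_nadh",
                        gapdh_sites_uM = sites, noise_sd = noise_sd,
                        v_true = v_true)
}
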