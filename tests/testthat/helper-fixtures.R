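# Shared fixtures: everything is generated in code at test time.

# Screen-format protocol: 10 s baseline, 50 s contact, 60 s dissociation, 1 Hz
screen_protocol <- function() injection_protocol(50, 60)

# Protein-ligand / reducing-agent format: 180 s contact, 600 s dissociation
ligand_protocol <- function() injection_protocol(180, 600)

default_surface <- function(activity = 1)
  surface_model(protein_mw = 55000, capture_level = 16000,
                stoichiometry = 1, activity_fraction = activity)

# A well-behaved fragment binder: KD 2.5 uM, moderately fast kinetics
clean_binder <- function(rmax = 40) kinetic_params(ka = 2e4, kd = 0.05, rmax = rmax)

# Kinetic parameters from an affinity and a dissociation half-life
params_from_kd <- function(kd_eq, t_half_s, rmax = 60)
  kinetic_params(ka = (log(2) / t_half_s) / kd_eq, kd = log(2) / t_half_s,
                 rmax = rmax)

two_fold_series <- function(top, n = 6) top / 2^(seq_len(n) - 1)

# Independent brute-force Tanimoto on a library's fingerprints
brute_force_max_tanimoto <- function(library) {
  fps <- lapply(library$fingerprint, fp_from_hex)
  n <- length(fps)
  if (n < 2) return(0)
  best <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    u <- sum(fps[[i]] | fps[[j]])
    s <- if (u == 0) 1 else sum(fps[[i]] & fps[[j]]) / u
    best <- max(best, s)
  }
  best
}
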