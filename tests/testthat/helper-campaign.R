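# Shared, lazily computed campaign results for the acceptance tests.
# Legs are cached per (ion, n) so different test blocks reuse them.

.camp <- new.env(parent = emptyenv())

camp_steps <- function() 40000L        # 40 ps per window in the test suite
camp_kf <- function() 1000             # top of the default kf grid

camp_memo <- function(key, fn) {
  if (is.null(.camp[[key]])) .camp[[key]] <- fn()
  .camp[[key]]
}

camp_r_opt <- function(ion, n) {
  camp_memo(paste0("ropt_", ion, n), function()
    find_r_opt(ion, n, nsteps = 60000, seed = 101)$r_opt)
}

camp_leg <- function(ion, n, seed_off = 0) {
  camp_memo(paste0("leg_", ion, n, "_", seed_off), function() {
    anchors <- cage_anchors(ion, n, camp_r_opt(ion, n))
    run_restraint_morph(ion, n, camp_kf(), anchors,
                        seed = 7000 + 13 * n + seed_off,
                        nsteps_per_window = camp_steps())
  })
}

camp_ion_leg <- function(from, to, n) {
  camp_memo(paste0("ionleg_", from, to, n), function()
    run_ion_morph(n, from, to, seed = 8000 + n,
                  nsteps_per_window = camp_steps(),
                  r_start = camp_r_opt(from, n)))
}

# Full cycle for pair (A, B) at the top-of-grid kf.
camp_cycle <- function(A, B, n) {
  camp_memo(paste0("cycle_", A, B, n), function()
    assemble_cycle(camp_leg(A, n), camp_leg(B, n), camp_ion_leg(B, A, n)))
}

# Transporter-site cycle for the Na/K pair at a given kf.
camp_site_cycle <- function(site, kf) {
  camp_memo(paste0("site_", site, "_", kf), function() {
    mk <- function(ion) {
      if (kf == 0) return(run_restraint_morph(ion, kf_target = 0, seed = 2))
      sys <- build_site_model(site, ion, kf = kf, dual_sets = TRUE)
      run_restraint_morph(ion, kf_target = kf, system = sys,
                          seed = 9000 + nchar(site) + match(ion, c("Li", "Na", "K")),
                          nsteps_per_window = camp_steps())
    }
    legNa <- mk("Na"); legK <- mk("K")
    free <- camp_memo(paste0("sitefree_", site), function()
      build_site_model(site, "K", kf = 0))
    ion_leg <- camp_memo(paste0("siteion_", site), function()
      run_ion_morph(ion_from = "K", ion_to = "Na", system = free, seed = 77,
                    nsteps_per_window = camp_steps()))
    assemble_cycle(legNa, legK, ion_leg)
  })
}
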