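# Shared, lazily computed fixtures (solves are deterministic; computed once
# per test run and reused across files).

.fix <- new.env(parent = emptyenv())

fix_get <- function(name, fun) {
  if (is.null(.fix[[name]])) .fix[[name]] <- fun()
  .fix[[name]]
}

fix_recoil <- function(rate) {
  fix_get(paste0("recoil_", rate), function()
    solve_recoil(assemble_treated(fp = fet_params(rate))))
}

fix_waveform <- function() fix_get("waveform", make_waveform)

fix_bank <- function() fix_get("bank", function()
  calibrate_windkessel(fix_waveform()))

# full seven-rate sweep at the coarse preset (disk-cached inside tempdir as
# well, so repeated test runs in one session reuse stage results)
fix_sweep7 <- function() fix_get("sweep7", function() {
  cfg <- default_config()
  cfg$rates <- seq(0, 0.30, by = 0.05)
  cfg$output_dir <- file.path(tempdir(), "fetsim-tests-sweep")
  run_sweep(cfg)
})

fix_baseline <- function() fix_get("baseline", function()
  solve_transient(list(type = "axisym_tube", R = 0.015, L = 0.3),
                  fix_waveform(), fix_bank(), n_cycles = 2,
                  nz = 60, nr = 24))
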