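# Shared fixture builders: everything is generated in code, no stored data.

# A reduced three-behavior scenario (plus the quiet-standing reference) that
# keeps module tests fast while exercising bout boundaries and both devices.
tiny_signatures <- function(noise_sd = 0.05) {
  d <- default_signatures()
  sigs <- d[c("STA", "FEG", "WAL", "STA_STILL")]
  for (nm in c("STA", "FEG", "WAL")) sigs[[nm]]$noise_sd <- noise_sd
  sigs
}

tiny_scenario <- function(individuals = c("a", "b"), seed = 42,
                          session_length = 2400, ...) {
  scenario_config(individuals = individuals, signatures = tiny_signatures(),
                  session_length = session_length, seed = seed, ...)
}

# A synthetic burst with arbitrary values (for parser/feature/metric tests
# that do not need a realistic signal).
make_burst <- function(individual = "x", label = "STA", start = 0, n = 82,
                       center = 2048, sd = 40, device = "burst_logger") {
  acc_burst(individual, device, start,
            sway = round(rnorm(n, center, sd)),
            surge = round(rnorm(n, center, sd)),
            heave = round(rnorm(n, center, sd)), label = label)
}

# n bursts per label in `counts`, e.g. counts = c(STA = 120, WAL = 45).
make_dataset <- function(counts, individual = "x") {
  bursts <- list()
  for (lab in names(counts))
    for (k in seq_len(counts[[lab]]))
      bursts <- c(bursts, list(make_burst(individual, lab,
                                          start = 20 * length(bursts))))
  filter_pure(bursts, device = "burst_logger")
}
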