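# One shared study-design emulation run for the qualitative end-to-end checks;
# built lazily and cached for the session.
emulation_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- experiment_config(seed = 101,
                               out_dir = file.path(tempdir(), "emulation_run"))
      cache <<- suppressMessages(suppressWarnings(run_experiment(cfg)))
    }
    cache
  }
})
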