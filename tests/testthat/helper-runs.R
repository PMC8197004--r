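# Memoized full-resolution plateau runs shared by the acceptance tests.
.run_cache <- new.env(parent = emptyenv())

plateau_run <- function(toc, t_end = 5300) {
  key <- sprintf("toc_%g_t_%g", toc, t_end)
  if (!exists(key, envir = .run_cache)) {
    cfg <- default_config(c0_toc = toc)
    assign(key,
           run_simulation(cfg, t_end = t_end,
                          snapshot_times = c(100, t_end), verbose = FALSE),
           envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

series_at <- function(result, t) {
  s <- result$series
  s[which.min(abs(s$t_s - t)), ]
}
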