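#!/usr/bin/env Rscript
# Random-responder null: how often would an observer answering at chance on
# every trial survive the both-sessions-out-of-range exclusion rule? The
# full-scale run (n = 5000) lives in scripts/acceptance.R; this driver uses
# n = 1000 for a quick desk check and reports a binomial CI.

suppressPackageStartupMessages(library(illumdisc))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

series <- build_illuminant_series()
n <- 1000
null <- random_responder_null(n, series, seed = 77, progress_every = 250)
ci <- binom.test(null$n_excluded, n)$conf.int
cat(sprintf("excluded %d / %d random responders (%.2f%%; 95%% CI %.2f-%.2f%%)\n",
            null$n_excluded, n, 100 * null$fraction_excluded,
            100 * ci[1], 100 * ci[2]))
jsonlite::write_json(
  list(n_observers = n, n_excluded = null$n_excluded,
       fraction_excluded = null$fraction_excluded,
       ci95 = ci),
  file.path(out_dir, "random_responder_null.json"),
  auto_unbox = TRUE, digits = NA
)
write.csv(null$detail, file.path(out_dir, "random_responder_detail.csv"),
          row.names = FALSE)
cat("wrote", file.path(out_dir, "random_responder_null.json"), "\n")
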