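#!/usr/bin/env Rscript
# Stage 2: fit the four model variants to the training split by MCMC.
#
# Desk-scale chains (3 x 20,000, burn-in 10,000) for the fixed-effect
# variants M1/M2; the person-level random-effect variants M3/M4 get the
# same chains but are the slow, weakly identified ones the model
# comparison is designed to expose. Posterior summaries mirror the usual
# mean / median / equal-tailed 95% interval / PSRF table.

suppressPackageStartupMessages(library(fevertreat))

frame <- utils::read.csv("results/model_frame.csv")
split <- split_records(frame, validation_fraction = 0.4, seed = 2027)
utils::write.csv(split$train, "results/train.csv", row.names = FALSE)
utils::write.csv(split$validation, "results/validation.csv",
                 row.names = FALSE)
cat(sprintf("Split: %d training / %d validation records\n",
            nrow(split$train), nrow(split$validation)))

fits <- list()
summaries <- list()
for (v in c("M1", "M2", "M3", "M4")) {
  t0 <- Sys.time()
  fits[[v]] <- run_mcmc(split$train, v,
                        config = chain_config(3, 20000, 10000,
                                              seed = 2030 + match(v, c("M1", "M2", "M3", "M4"))))
  s <- cbind(variant = v, summarise_draws(fits[[v]]))
  summaries[[v]] <- s
  cat(sprintf("%s fitted in %.0f s; max PSRF %.3f\n", v,
              as.numeric(Sys.time() - t0, units = "secs"),
              max(s$psrf_point)))
}
utils::write.csv(do.call(rbind, summaries), "results/posterior_summaries.csv",
                 row.names = FALSE)

# persist draws (long format, thinned) for later stages and external tools
for (v in names(fits)) {
  write_draws(fits[[v]], sprintf("results/draws_%s.csv", v), thin = 10L)
}

dics <- lapply(fits, function(f) dic(split$train, f))
tab <- model_comparison_table(dics, n_chains = 3)
print(tab)
utils::write.csv(tab, "results/model_comparison.csv", row.names = FALSE)
saveRDS(fits, "results/fits.rds")  # intermediate only; regenerated by rerun
cat(sprintf("Effective parameters (pD): %s — the individual-level random-effect\n",
            paste(sprintf("%s %.1f", tab$variant, tab$pd), collapse = ", ")))
cat("variants absorb record-level noise and pay a large complexity penalty\n")
cat("relative to their five-parameter fixed-effect counterparts.\n")
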