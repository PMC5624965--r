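# Regenerates the frozen oracle impact fixtures under tests/testthat/fixtures/.
test_path <- function(...) file.path("tests/testthat", ...)
source("tests/testthat/helper-oracle.R")
per <- oracle_simulate(forcing_fn = oracle_forcing_periodic)
imp <- oracle_simulate(forcing_fn = oracle_forcing_impulsive)
fmt <- function(df) { df[] <- lapply(df, function(x) sprintf("%.12f", x)); df }
write.csv(fmt(per), "tests/testthat/fixtures/fig2-periodic_impacts.csv",
          row.names = FALSE, quote = FALSE)
write.csv(fmt(imp), "tests/testthat/fixtures/fig2-impulsive_impacts.csv",
          row.names = FALSE, quote = FALSE)
cat("periodic n =", nrow(per), " impulsive n =", nrow(imp), "\n")
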