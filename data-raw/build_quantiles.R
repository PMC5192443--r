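# Builds the bundled default quantile tables shipped in inst/extdata.
# Run from the package root:  Rscript data-raw/build_quantiles.R
devtools::load_all(".", quiet = TRUE)

db <- simulate_formula_db(20000, c(50, 1000), seed = 1)
records <- compound_ratios(db, resolution = 10000, max_isotopes = 5)
tables <- build_quantile_tables(records, window_size = 50,
                                source_name = "synthetic_db_n20000_seed1")
write_quantile_table(tables, "inst/extdata/quantiles_synthetic_db_w50.json")
cat("windows populated:", sum(tables[["1"]]$counts > 0), "/",
    length(tables[["1"]]$counts), "\n")
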