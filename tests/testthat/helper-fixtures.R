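# Shared, lazily built (and then cached) simulation fixtures.  All seeds are
# fixed constants; scenario scales are stated in the methods vignette.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env))
    assign(name, builder(), envir = fixture_env)
  get(name, envir = fixture_env)
}

# Small genome for module-level pipeline tests: fast, but large enough that
# every filter stage has material to act on.
small_cfg <- function(...) {
  base <- list(chrom_lengths = c(chr1 = 30000, chr2 = 28000, chr3 = 26000,
                                 chr4 = 25000, chrX = 15000, chrY = 10000),
               telomere_length = 300, centromere_length = 600,
               par_length = 800, repeat_block = 200, sample_depth = 6,
               control_depth = 20, n_controls = 2, n_reference = 24,
               n_euploid_test = 4, n_trisomic_test = 2,
               trisomy_chrom = "chr4")
  do.call(sim_config, modifyList(base, list(...)))
}

small_scenario <- function() {
  fixture("small_scenario", function() simulate_scenario(small_cfg(), seed = 90001))
}

small_lists <- function() {
  fixture("small_lists", function() {
    sc <- small_scenario()
    build_chromosome_lists(
      sc$sim$genome, variants = sc$variants,
      regions = sc$sim$regions[, c("chrom", "start", "end")],
      controls = sc$controls, k = sc$config$k)
  })
}

small_result <- function() {
  fixture("small_result", function() {
    sc <- small_scenario()
    lists <- small_lists()
    counts <- simulate_cohort_counts(sc, lists)
    mat <- build_nipt_matrix(counts, lists)
    plan <- sc$plan
    model <- nipt_model(mat, reference = plan$sample_id[plan$role == "reference"],
                        fetal_sex = setNames(plan$fetal_sex, plan$sample_id))
    list(scenario = sc, lists = lists, matrix = mat, model = model,
         calls = predict(model, mat), plan = plan)
  })
}

# Full-scale cohort at the package's default study conditions; used by the
# end-to-end and filter-correctness acceptance checks.
e2e_result <- function() {
  fixture("e2e", function() {
    sc <- simulate_scenario(sim_config(), seed = 104729)
    res <- run_scenario(sc)
    res$scenario <- sc
    res
  })
}

# Plain synthetic coverage matrix (no reads) for direct model-level tests.
synthetic_matrix <- function(n = 40, chroms = paste0("chr", 1:5),
                             L = 1000, seed = 1, depth_range = c(0.5, 1.5)) {
  set.seed(seed)
  depth <- runif(n, depth_range[1], depth_range[2])
  K <- vapply(chroms, function(ch)
    round(depth * L * (1 + rnorm(n, 0, 0.01))), numeric(n))
  df <- data.frame(sample_id = sprintf("T%03d", seq_len(n)), K,
                   gc = 0.5 + rnorm(n, 0, 0.002), check.names = FALSE)
  structure(df, L_c = setNames(rep(L, length(chroms)), chroms),
            k = 25L, digest = "synthetic", mode = "occurrences",
            class = c("nipt_matrix", "data.frame"))
}
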