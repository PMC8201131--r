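# Abundance normalization, ratio classification, paralog responses,
# binary layer construction.

make_abundance <- function(values, proteins = NULL, subunit = "60S",
                           sample = "s1") {
  if (is.null(proteins)) proteins <- sprintf("uL%02d", seq_along(values))
  tibble::tibble(protein = proteins, subunit = subunit, sample = sample,
                 abundance = values)
}

test_that("subunit normalization yields unit sums and forced values", {
  one <- normalize_by_subunit(make_abundance(5))
  expect_equal(one$nx, 1)
  two <- normalize_by_subunit(make_abundance(c(3, 1)))
  expect_equal(two$nx, c(0.75, 0.25))
  # subunits normalize independently within a sample
  mixed <- dplyr::bind_rows(
    make_abundance(c(2, 2), subunit = "60S"),
    make_abundance(c(1, 3), proteins = c("uS01", "uS02"),
                   subunit = "40S"))
  nx <- normalize_by_subunit(mixed)
  expect_equal(sum(nx$nx[nx$subunit == "60S"]), 1)
  expect_equal(sum(nx$nx[nx$subunit == "40S"]), 1)
})

test_that("normalization conserves unit sums on random fixtures", {
  withr::with_seed(31, {
    long <- tidyr::expand_grid(protein = sprintf("p%02d", 1:20),
                               sample = sprintf("s%d", 1:6)) |>
      dplyr::mutate(subunit = ifelse(substr(protein, 2, 3) < "11",
                                     "40S", "60S"),
                    abundance = stats::rlnorm(dplyr::n(), 10, 1))
  })
  nx <- normalize_by_subunit(long)
  sums <- nx |>
    dplyr::group_by(sample, subunit) |>
    dplyr::summarise(s = sum(nx), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("an all-zero subunit names the offending sample", {
  bad <- make_abundance(c(0, 0), sample = "s9")
  err <- expect_error(normalize_by_subunit(bad),
                      class = "structenrich_normalization_error")
  expect_match(conditionMessage(err), "s9")
})

test_that("60S:polysome ratios reproduce hand-computed values", {
  reps <- 1:3
  base <- tidyr::expand_grid(protein = c("uL01", "uL02"),
                             replicate = reps,
                             fraction = c("60S", "polysome")) |>
    dplyr::mutate(genotype = "Col-0", temperature = "10C",
                  sample = paste(fraction, replicate, sep = "_"),
                  subunit = "60S")
  # identical profiles: all ratios zero
  same <- dplyr::mutate(base, nx = 0.5)
  r0 <- ln_ratio_60s_polysome(same)
  expect_equal(r0$ln_ratio, c(0, 0))

  # known means: uL01 nx 0.6 in 60S vs 0.3 in polysome
  known <- dplyr::mutate(base, nx = dplyr::case_when(
    protein == "uL01" & fraction == "60S" ~ 0.6,
    protein == "uL01" ~ 0.3,
    fraction == "60S" ~ 0.4,
    TRUE ~ 0.7))
  rk <- ln_ratio_60s_polysome(known)
  expect_equal(rk$ln_ratio[rk$protein == "uL01"], log(0.6 / 0.3),
               tolerance = 1e-12)
  expect_equal(rk$ln_ratio[rk$protein == "uL02"], log(0.4 / 0.7),
               tolerance = 1e-12)
})

test_that("proteins missing from any replicate are filtered out", {
  reps <- 1:3
  base <- tidyr::expand_grid(protein = c("uL01", "uL02"),
                             replicate = reps,
                             fraction = c("60S", "polysome")) |>
    dplyr::mutate(genotype = "g", temperature = "t",
                  sample = paste(fraction, replicate, sep = "_"),
                  subunit = "60S", nx = 0.5)
  base$nx[base$protein == "uL02" & base$fraction == "polysome" &
            base$replicate == 2] <- NA
  r <- ln_ratio_60s_polysome(base)
  expect_equal(r$protein, "uL01")
  # and an empty result warns
  empty <- base[base$protein == "uL02", ]
  expect_warning(ln_ratio_60s_polysome(empty), "complete-presence")
})

test_that("ratio classes follow the display bins", {
  expect_equal(classify_ratio(0.5), "increase")
  expect_equal(classify_ratio(1), "increase")       # boundary r <= 1
  expect_equal(classify_ratio(1.5), "high_increase")
  expect_equal(classify_ratio(0), "no_change")
  expect_equal(classify_ratio(-0.5), "decrease")
  expect_equal(classify_ratio(-1), "decrease")      # boundary r >= -1
  expect_equal(classify_ratio(c(2, 2.5, -1.01)),
               rep("out_of_range", 3))
  expect_error(classify_ratio(Inf),
               class = "structenrich_validation_error")
})

test_that("family responses implement the three paralog scenarios", {
  expect_equal(classify_family_response(c("up", "none", "none")),
               "up_only")
  expect_equal(classify_family_response(c("down", "down")), "down_only")
  expect_equal(classify_family_response(c("up", "down")), "inverse")
  expect_equal(classify_family_response(c("none", "none")), "unchanged")
  # permutation invariance
  withr::with_seed(8, {
    for (i in 1:20) {
      dirs <- sample(c("up", "down", "none"), 5, replace = TRUE)
      expect_equal(classify_family_response(dirs),
                   classify_family_response(sample(dirs)))
    }
  })
  expect_error(classify_family_response("sideways"),
               class = "structenrich_validation_error")
})

test_that("binary layers implement containment and union rules", {
  nodes <- c("uL30", "uL3", "eL22", "uS2")
  responses <- tibble::tibble(
    family = c("uL30", "uL3", "eL22"),
    scenario = c("inverse", "up_only", "down_only"))
  layers <- build_binary_layers(responses,
                                ratio_significant = "uL3",
                                polysome_significant = "eL22",
                                nodes = nodes)
  get <- function(l, p) layers$call[layers$layer_id == l &
                                      layers$protein == p]
  # inverse family: in all transcript layers
  expect_equal(c(get("1T", "uL30"), get("2T", "uL30"),
                 get("3T", "uL30")), c(1, 1, 1))
  # up_only: excluded from 1T, included from 2T on
  expect_equal(c(get("1T", "uL3"), get("2T", "uL3"), get("3T", "uL3")),
               c(0, 1, 1))
  # down_only: only 3T
  expect_equal(c(get("2T", "eL22"), get("3T", "eL22")), c(0, 1))
  # proteome: 1P-only protein is called in 3P
  expect_equal(c(get("1P", "uL3"), get("2P", "uL3"), get("3P", "uL3")),
               c(1, 0, 1))
  expect_equal(c(get("2P", "eL22"), get("3P", "eL22")), c(1, 1))
  # untouched node is zero everywhere
  expect_true(all(layers$call[layers$protein == "uS2"] == 0))
})

test_that("layer nesting holds for arbitrary scenario draws", {
  withr::with_seed(77, {
    for (i in 1:10) {
      nodes <- sprintf("F%02d", 1:15)
      responses <- tibble::tibble(
        family = nodes,
        scenario = sample(c("inverse", "up_only", "down_only",
                            "unchanged"), 15, replace = TRUE))
      ratio_sig <- sample(nodes, 4)
      poly_sig <- sample(nodes, 4)
      layers <- build_binary_layers(responses, ratio_sig, poly_sig,
                                    nodes)
      ones <- function(l) layers$protein[layers$layer_id == l &
                                           layers$call == 1]
      expect_true(all(ones("1T") %in% ones("2T")))
      expect_true(all(ones("2T") %in% ones("3T")))
      expect_true(all(ones("1P") %in% ones("3P")))
      expect_true(all(ones("2P") %in% ones("3P")))
    }
  })
})

test_that("unmappable families are reported and excluded", {
  responses <- tibble::tibble(family = c("uL30", "ghost"),
                              scenario = c("inverse", "inverse"))
  layers <- build_binary_layers(responses, nodes = c("uL30", "uL3"),
                                layers = c("1T"))
  expect_equal(attr(layers, "unmapped"), "ghost")
  expect_setequal(layers$protein, c("uL30", "uL3"))
})

test_that("binary layer TSVs round-trip", {
  layers <- build_binary_layers(
    tibble::tibble(family = "uL30", scenario = "inverse"),
    nodes = c("uL30", "uL3"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_binary_layers(layers, path)
  back <- read_binary_layers(path)
  expect_equal(back$call, layers$call)
  expect_equal(back$protein, layers$protein)
})

test_that("wide abundance matrices join their sample sheet", {
  wide <- tibble::tibble(protein = c("uL01", "uL02"), subunit = "60S",
                         s1 = c(1, 2), s2 = c(3, 4))
  samples <- tibble::tibble(sample = c("s1", "s2"), genotype = "Col-0",
                            temperature = "10C",
                            fraction = c("60S", "polysome"),
                            replicate = 1L)
  pa <- withr::local_tempfile(fileext = ".tsv")
  ps <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(wide, pa)
  readr::write_tsv(samples, ps)
  long <- read_abundance_matrix(pa, ps)
  expect_equal(nrow(long), 4)
  expect_true(all(c("genotype", "fraction", "abundance") %in%
                    names(long)))
})
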