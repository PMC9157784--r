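test_that("station-level records collapse to unit-level presence", {
  sp <- small_species(c("x", "y"))
  un <- unit_table(data.frame(unit_id = c("A", "B")))
  rec <- data.frame(unit_id = c("A", "A"), station_id = c("s1", "s3"),
                    species_code = c("x", "x"))
  inc <- read_incidence(rec, sp, un)
  expect_identical(dim(inc$presence), c(2L, 2L))
  expect_true(inc$presence["A", "x"])
  expect_false(any(inc$presence["B", ]))
  expect_false(inc$presence["A", "y"])
})

test_that("unknown codes are hard errors naming the code", {
  sp <- small_species("x")
  un <- unit_table(data.frame(unit_id = "A"))
  expect_error(read_incidence(data.frame(unit_id = "A", species_code = "zzz"),
                              sp, un), "zzz")
  expect_error(read_incidence(data.frame(unit_id = "Q", species_code = "x"),
                              sp, un), "Q")
})

test_that("duplicate (unit, species) rows collapse silently", {
  sp <- small_species(c("a", "b", "c"))
  un <- unit_table(data.frame(unit_id = c("u1", "u2", "u3")))
  rec <- data.frame(unit_id = c("u1", "u1", "u1", "u2", "u3"),
                    species_code = c("a", "a", "b", "c", "a"))
  inc <- read_incidence(rec, sp, un)
  expect_identical(sum(inc$presence), 4L)  # one duplicate collapsed
})

test_that("tally_counts reproduces hand counts and the saturated case", {
  sat <- incidence_matrix(matrix(TRUE, 4, 3))
  cs <- tally_counts(sat)
  expect_identical(cs$Q1, 0L)
  expect_identical(cs$Q2, 0L)
  expect_identical(cs$incidences, cs$m * cs$Sobs)

  set.seed(1)
  mm <- matrix_with_frequencies(c(3, 1, 1, 2), m = 5)
  ct <- tally_counts(mm)
  expect_identical(ct$Sobs, 4L)
  expect_identical(ct$Q1, 2L)
  expect_identical(ct$Q2, 1L)
  expect_identical(ct$incidences, 7L)
  expect_error(tally_counts(matrix(logical(0), 0, 0)), "empty")
})

test_that("tally_counts is invariant to unit and species permutation", {
  set.seed(42)
  for (i in 1:5) {
    inc <- random_matrix(m = 7, S = 9)
    ct <- tally_counts(inc)
    perm <- inc$presence[sample(nrow(inc$presence)), sample(ncol(inc$presence))]
    ct2 <- tally_counts(perm)
    expect_identical(ct[c("m", "incidences", "Sobs", "Q1", "Q2")],
                     ct2[c("m", "incidences", "Sobs", "Q1", "Q2")])
    expect_identical(sort(unname(ct$per_species)), sort(unname(ct2$per_species)))
    expect_lte(ct$Q1 + ct$Q2, ct$Sobs)
    expect_lte(ct$Sobs, ct$m * max(rowSums(inc$presence)))
  }
})

test_that("long-form ingestion equals the equivalent wide form", {
  set.seed(7)
  inc <- random_matrix(m = 6, S = 5)
  long <- which(inc$presence, arr.ind = TRUE)
  rec <- data.frame(unit_id = rownames(inc$presence)[long[, 1]],
                    species_code = colnames(inc$presence)[long[, 2]])
  from_long <- read_incidence(rec, inc$species, inc$units)
  expect_identical(tally_counts(from_long)$per_species,
                   tally_counts(inc)$per_species)
})

test_that("endpoint summary applies the strict rarity rule per fraction", {
  # 4 units, frequencies {4,1,1}, one non-native; total incidence 6
  sp <- small_species(c("a", "b", "c"), origin = c("native", "native", "non_native"))
  pres <- rbind(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE),
                c(TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE))
  colnames(pres) <- c("a", "b", "c"); rownames(pres) <- paste0("u", 1:4)
  inc <- incidence_matrix(pres, species = sp)
  es <- endpoint_summary(inc)
  expect_equal(es$mean_richness[es$endpoint == "total"], 1.5)
  # rare-5 threshold is 0.05 * 6 = 0.3: no frequency is below it
  expect_equal(es$mean_richness[es$endpoint == "rare_5"], 0)
  # rare-20 threshold 1.2: the two uniques qualify
  expect_equal(es$mean_richness[es$endpoint == "rare_20"], 0.5)
  expect_equal(es$mean_richness[es$endpoint == "non_native"], 0.25)
  expect_error(endpoint_summary(inc, rare_fractions = 1.2), "strictly inside")
})

test_that("endpoint means satisfy their ordering invariants", {
  set.seed(11)
  for (i in 1:5) {
    origin <- sample(c("native", "non_native"), 8, replace = TRUE,
                     prob = c(0.8, 0.2))
    inc <- random_matrix(6, 8,
                         species = small_species(paste0("sp", 1:8), origin))
    es <- endpoint_summary(inc)
    tot <- es$mean_richness[es$endpoint == "total"]
    expect_lte(es$mean_richness[es$endpoint == "rare_5"], tot)
    expect_lte(es$mean_richness[es$endpoint == "non_native"], tot)
  }
})

test_that("all-native communities report zero non-native richness", {
  set.seed(2)
  inc <- random_matrix(5, 4)
  es <- endpoint_summary(inc)
  expect_equal(es$mean_richness[es$endpoint == "non_native"], 0)
})

test_that("native/non-native correlation handles exact and degenerate cases", {
  sp <- small_species(c("n1", "n2", "e1", "e2"),
                      origin = c("native", "native", "non_native", "non_native"))
  # native == non_native per unit -> r = 1
  pres <- rbind(c(TRUE, TRUE, TRUE, TRUE), c(TRUE, FALSE, TRUE, FALSE),
                c(FALSE, FALSE, FALSE, FALSE))
  dimnames(pres) <- list(paste0("u", 1:3), sp$code)
  expect_equal(native_nonnative_relationship(incidence_matrix(pres, sp))$r, 1)
  # anti-balanced: native 2,1,0 vs non-native 0,1,2 -> r = -1
  pres2 <- rbind(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE),
                 c(FALSE, FALSE, TRUE, TRUE))
  dimnames(pres2) <- list(paste0("u", 1:3), sp$code)
  expect_equal(native_nonnative_relationship(incidence_matrix(pres2, sp))$r, -1)
  # zero variance -> undefined, not 0
  pres3 <- rbind(c(TRUE, FALSE, TRUE, FALSE), c(TRUE, FALSE, FALSE, TRUE),
                 c(FALSE, TRUE, TRUE, FALSE))
  dimnames(pres3) <- list(paste0("u", 1:3), sp$code)
  expect_true(is.na(native_nonnative_relationship(incidence_matrix(pres3, sp))$r))
})

test_that("euphotic depth is the Secchi multiple, warning outside 2-3x", {
  expect_equal(euphotic_depth(1.5, 2), 3.0)
  expect_equal(euphotic_depth(3.6, 3), 10.8)
  expect_equal(euphotic_depth(1.5, 3), 4.5)
  expect_warning(euphotic_depth(1.5, 4), "range")
  expect_error(euphotic_depth(-1, 2), "positive")
})
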