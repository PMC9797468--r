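ped_df <- function(fathers_by_litter, mother = "m1") {
  rows <- list()
  pid <- 0L
  for (li in seq_along(fathers_by_litter)) {
    for (f in fathers_by_litter[[li]]) {
      pid <- pid + 1L
      rows[[pid]] <- data.frame(offspring_id = paste0("p", pid),
                                mother_id = mother, father_id = f,
                                delivery_time = li * 30 * DAY,
                                litter_id = paste0("L", li),
                                stringsAsFactors = FALSE)
    }
  }
  as_pedigree(do.call(rbind, rows))
}

test_that("multiple paternity follows the sibling-pair closed form", {
  # every litter single-sired -> 0
  expect_equal(multiple_paternity(ped_df(list(c("f1", "f1", "f1"),
                                              c("f2", "f2")))), 0)
  # one litter of two with different fathers -> 1
  expect_equal(multiple_paternity(ped_df(list(c("f1", "f2")))), 1)
  # litters {AAB} and {AA}: (2/3 + 0) / 2 = 1/3
  expect_equal(multiple_paternity(ped_df(list(c("A", "A", "B"), c("A", "A")))),
               1 / 3, tolerance = 1e-12)
  # singletons and unassigned-father litters are excluded entirely
  expect_equal(multiple_paternity(ped_df(list(c("A", "A", "B"), "C",
                                              c("D", NA)))), 2 / 3)
  expect_true(is.na(multiple_paternity(ped_df(list("A", c("B", NA))))))
})

test_that("multiple paternity agrees with the Monte-Carlo pair oracle", {
  set.seed(14)
  fathers <- replicate(12, sample(paste0("f", 1:4), sample(2:6, 1),
                                  replace = TRUE), simplify = FALSE)
  ped <- ped_df(fathers)
  exact <- multiple_paternity(ped)
  draws <- 1e5
  mc <- mc_multiple_paternity(ped, draws)
  se <- sqrt(mc * (1 - mc) / draws)
  expect_lt(abs(exact - mc), 3 * se + 1e-12)
})

test_that("bond persistence counts within-module parentage arrows", {
  ped <- as_pedigree(data.frame(
    offspring_id = c("o1", "o2", "o3", "o4"),
    mother_id = c("m1", "m1", "m2", "m2"),
    father_id = c("f1", NA, "f2", "f2"),
    delivery_time = 100, litter_id = c("L1", "L1", "L2", "L2"),
    stringsAsFactors = FALSE))
  part <- data.frame(
    tag_id = c("m1", "m2", "f1", "f2", "o1", "o2", "o3", "o4"),
    layer_index = 1L,
    module_id = c(1, 2, 1, 2, 1, 1, 2, 1), stringsAsFactors = FALSE)
  # arrows with both assigned: m1->o1, m1->o2, m2->o3, m2->o4, f1->o1,
  # f2->o3, f2->o4; within-module: all but m2->o4 and f2->o4 -> 5/7
  expect_equal(bond_persistence(ped, part, 1L), 5 / 7)

  # all co-assigned -> 1; sole arrow split -> 0
  part1 <- part; part1$module_id <- 1
  expect_equal(bond_persistence(ped, part1, 1L), 1)
  solo <- as_pedigree(data.frame(offspring_id = "o1", mother_id = "m1",
                                 father_id = NA, delivery_time = 1,
                                 litter_id = "L1", stringsAsFactors = FALSE))
  psplit <- data.frame(tag_id = c("m1", "o1"), layer_index = 1L,
                       module_id = c(1, 2))
  expect_equal(bond_persistence(solo, psplit, 1L), 0)

  # unassigned members are excluded; none assigned -> NA
  expect_true(is.na(bond_persistence(solo, psplit[1, ], 1L)))

  # sex-specific filters use offspring sex
  inds <- data.frame(tag_id = c("o1", "o2", "o3", "o4"),
                     sex = c("F", "M", "F", "M"), stringsAsFactors = FALSE)
  # mother-daughter arrows: m1->o1 (same), m2->o3 (same) -> 1
  expect_equal(bond_persistence(ped, part, 1L, "mother-daughter", inds), 1)
  # father-son arrows: f2->o4 (split) -> 0
  expect_equal(bond_persistence(ped, part, 1L, "father-son", inds), 0)
})

test_that("deme support reproduces the ten-layer worked example", {
  fx <- make_fixture("nora_miro")
  # conception (delivery - 20 d) falls in layer 6; window = layers 6..15
  lt <- litter_table(fx$pedigree, fx$layers)
  expect_equal(lt$conception_layer, 6)
  expect_equal(lt$conception_time, 10.5 * DAY)

  ds_full <- deme_support(fx$pedigree, fx$partition_full, fx$layers)
  expect_equal(ds_full$litters$n_window_layers, 10)
  expect_equal(ds_full$litters$support, 1.0)

  ds_part <- deme_support(fx$pedigree, fx$partition_partial, fx$layers)
  expect_equal(ds_part$litters$support, 0.2)
})

test_that("effective pairs add litter supports per module", {
  fx <- make_fixture("nora_miro")
  # one pair conceiving twice with full association counts as two pairs
  ped2 <- as_pedigree(rbind(as.data.frame(fx$pedigree),
    data.frame(offspring_id = c("pup4", "pup5"), mother_id = "nora",
               father_id = "miro", delivery_time = 30.5 * DAY,
               litter_id = "L002", stringsAsFactors = FALSE)))
  ds2 <- deme_support(ped2, fx$partition_full, fx$layers)
  expect_equal(ds2$modules$effective_pairs[ds2$modules$module_id == 1], 2)
  expect_true(ds2$modules$is_deme[ds2$modules$module_id == 1])

  # two pairs, each with half association, count as one
  # second couple in module 1 only during window layers 6-10 (5 of 10)
  half2 <- data.frame(tag_id = rep(c("vera", "milo"), each = 20),
                      layer_index = rep(1:20, 2), stringsAsFactors = FALSE)
  half2$module_id <- ifelse(half2$layer_index %in% 6:10, 1L, 3L)
  # nora/miro likewise restricted to layers 6-10
  halfnm <- fx$partition_full
  halfnm$module_id <- ifelse(halfnm$layer_index %in% 6:10, 1L, 2L)
  part <- rbind(halfnm, half2)
  ped3 <- as_pedigree(rbind(as.data.frame(fx$pedigree),
    data.frame(offspring_id = "pup9", mother_id = "vera",
               father_id = "milo", delivery_time = 30.5 * DAY,
               litter_id = "L009", stringsAsFactors = FALSE)))
  ds3 <- deme_support(ped3, part, fx$layers)
  expect_equal(ds3$modules$effective_pairs[ds3$modules$module_id == 1], 1)

  # a module never supported by reproduction is not a deme
  expect_false(any(ds3$modules$is_deme[ds3$modules$module_id != 1]))

  # unassigned father: litter skipped with a warning
  pedna <- as_pedigree(data.frame(offspring_id = "x1", mother_id = "nora",
                                  father_id = NA, delivery_time = 30.5 * DAY,
                                  litter_id = "LX", stringsAsFactors = FALSE))
  expect_warning(dsna <- deme_support(pedna, fx$partition_full, fx$layers),
                 "father unassigned")
  expect_equal(nrow(dsna$litters), 0)
  expect_false(any(dsna$modules$is_deme))
})

test_that("unobserved parents count against support in the primary variant", {
  fx <- make_fixture("nora_miro")
  # remove miro from layers 8-15: joint assignment only in layers 6-7
  pt <- fx$partition_full
  pt <- pt[!(pt$tag_id == "miro" & pt$layer_index %in% 8:15), ]
  ds <- deme_support(fx$pedigree, pt, fx$layers)
  expect_equal(ds$litters$support, 0.2)          # denominator keeps 10 layers
  expect_equal(ds$litters$support_observed, 1.0) # observed-layers variant
})
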