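profile_for <- function(species, endemic, area, breadth, elev = 100,
                        zones = c(wet = 1)) {
  species_profile(species, endemic, area, breadth, elev, zones)
}

test_that("the five-way classification follows the stated rule order", {
  wide <- classify_endemism(profile_for("royenii-like", TRUE, 15993, 0.62))
  expect_equal(wide$label, "wide_endemic")
  expect_false(wide$overridden)

  montane <- classify_endemism(profile_for("cuneatum-like", TRUE, 4812, 0.11,
                                           elev = c(1800, 2400)))
  expect_equal(montane$label, "narrow_endemic_montane")

  lowland <- classify_endemism(profile_for("discolor-like", TRUE, 6094, 0.11,
                                           elev = c(40, 250)))
  expect_equal(lowland$label, "narrow_endemic_lowland")

  dry <- classify_endemism(profile_for("capitellatum-like", FALSE, 20169, 0.81,
                                       zones = c(wet = 0.2, dry = 0.7, arid = 0.1)))
  expect_equal(dry$label, "nonendemic_dry")

  wet <- classify_endemism(profile_for("clarkeanum-like", FALSE, 5656, 0.23,
                                       zones = c(wet = 0.8, dry = 0.2)))
  expect_equal(wet$label, "nonendemic_wet")

  # boundary profiles classify wide (cutoffs applied as >=)
  expect_equal(classify_endemism(profile_for("edge", TRUE, 14152, 0.50))$label,
               "wide_endemic")

  # anomalies demand explicit overrides
  expect_error(classify_endemism(profile_for("odd", TRUE, 9640, 0.53)),
               "unresolved-endemic")
  ov <- classify_endemism(profile_for("odd", TRUE, 9640, 0.53),
                          overrides = c(odd = "wide_endemic"))
  expect_true(ov$overridden)
  expect_equal(ov$label, "wide_endemic")
  expect_error(classify_endemism(
    profile_for("tied", FALSE, 100, 0.4, zones = c(wet = 0.5, dry = 0.5))),
    "tie error")
})

test_that("published species table is reproduced from published numbers", {
  # Levins breadth + current areas + endemism flags + the two shipped
  # overrides reproduce every published category label; montane species
  # get montane elevations, lowland species lowland ones
  tab1 <- memecylon_species()
  tab4 <- memecylon_habitat_areas()
  ov <- memecylon_category_overrides()
  for (i in seq_len(nrow(tab1))) {
    sp <- tab1$species[i]
    r4 <- tab4[tab4$species == sp, ]
    elev <- if (tab1$category[i] == "narrow_endemic_montane") c(400, 1800)
            else c(30, 250)
    zones <- if (tab1$category[i] == "nonendemic_dry")
      c(wet = 0.1, dry = 0.9) else c(wet = 0.9, dry = 0.1)
    got <- classify_endemism(
      profile_for(sp, tab1$endemic[i], r4$current_km2, r4$breadth,
                  elev = elev, zones = zones), overrides = ov)
    expect_equal(got$label, tab1$category[i], label = sp)
  }
})

test_that("richness stacks count overlapping members", {
  a <- matrix(0L, 4, 4); a[1:2, 1:4] <- 1L
  b <- matrix(0L, 4, 4); b[2:3, 1:3] <- 1L
  one <- stack_richness(list(a))
  expect_equal(one$counts, a)
  two <- stack_richness(list(a, b))
  expect_equal(sum(two$counts == 2, na.rm = TRUE), 3)  # row 2, cols 1..3
  expect_equal(two$max_count, 2)
  # NA only where every member is NA
  c2 <- b; c2[4, 4] <- NA
  expect_false(is.na(stack_richness(list(a, c2))$counts[4, 4]))
})

test_that("richness area honours the level and is antitone in it", {
  areas <- matrix(1, 4, 4)
  a <- matrix(0L, 4, 4); a[1:2, ] <- 1L
  b <- matrix(0L, 4, 4); b[2, 2:4] <- 1L
  rm2 <- stack_richness(list(a, b))
  expect_equal(richness_area(rm2, areas), 3)             # max level = 2
  expect_equal(richness_area(rm2, areas, level = 1), 8)
  expect_gte(richness_area(rm2, areas, level = 1),
             richness_area(rm2, areas))
  expect_equal(richness_area(stack_richness(list(a)), areas),
               sum(a))
})

test_that("uncertainty tri-state matches its truth table", {
  yes <- matrix(1L, 3, 3)
  no <- matrix(0L, 3, 3)
  # all replicates identical: no mixed cells anywhere
  u <- uncertainty_map(list(list(yes, yes), list(yes, yes)))
  expect_true(all(u == "always"))
  u0 <- uncertainty_map(list(list(no, no)))
  expect_true(all(u0 == "absent"))

  dissent <- yes; dissent[2, 2] <- 0L
  u1 <- uncertainty_map(list(list(yes, dissent)))
  expect_equal(u1[2, 2], "mixed")
  expect_true(all(u1[-5] == "always"))

  # absent = some member never predicts the cell
  gone <- no; gone[1, 1] <- 1L
  u2 <- uncertainty_map(list(list(yes, yes), list(gone, gone)))
  expect_equal(u2[1, 1], "always")
  expect_true(all(u2[-1] == "absent"))

  # always-cells are a subset of union-of-replicates cells
  set.seed(4)
  reps <- lapply(1:3, function(i)
    lapply(1:4, function(j) matrix(rbinom(9, 1, 0.6), 3, 3)))
  u3 <- uncertainty_map(reps)
  union_any <- Reduce(`|`, lapply(unlist(reps, recursive = FALSE), `==`, 1))
  expect_true(all(union_any[u3 == "always"]))
})
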