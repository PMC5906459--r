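test_that("snake traversal reverses direction each row, starting A1 left-to-right", {
  p96 <- plate_spec("96-medium")
  ord <- snake_order(p96)
  expect_equal(ord[1:12], paste0("A", 1:12))
  expect_equal(ord[13:24], paste0("B", 12:1))
  expect_equal(ord[25:36], paste0("C", 1:12))
  expect_equal(length(ord), 96)
  expect_false(anyDuplicated(ord) > 0)

  expect_equal(traversal_order(tiny_plate(1, 1), "snake"), "A1")
  expect_equal(traversal_order(tiny_plate(1, 1), "typewriter"), "A1")
  expect_equal(traversal_order(tiny_plate(2, 3), "typewriter"),
               c("A1", "A2", "A3", "B1", "B2", "B3"))
  # flipped starting direction
  expect_equal(snake_order(tiny_plate(2, 3), first_direction = "rtl"),
               c("A3", "A2", "A1", "B1", "B2", "B3"))
})

test_that("traversal orders are permutations of the well set on every format", {
  for (fmt in names(plate_formats())) {
    p <- plate_spec(fmt)
    for (pat in c("snake", "typewriter")) {
      ord <- traversal_order(p, pat)
      expect_setequal(ord, plate_wells(p))
      expect_equal(anyDuplicated(ord), 0L)
    }
  }
})

test_that("well naming round-trips and rejects malformed or out-of-bounds ids", {
  expect_equal(well_id(2, 7), "B7")
  pw <- parse_well(c("a1", "P24"))
  expect_equal(pw$well, c("A1", "P24"))
  expect_equal(pw$row, c(1L, 16L))
  expect_error(parse_well("Q1"), "malformed")
  expect_error(parse_well("A0"), "malformed|1-based")
  expect_error(parse_well("B7", tiny_plate(1, 3)), "outside")
})

test_that("alternating map splits the plate evenly and alternates along the order", {
  p22 <- tiny_plate(2, 2)
  m <- alternating_map(p22, "a", "b")
  asg <- m$assignments
  expect_equal(asg$fluid[match(c("A1", "A2", "B2", "B1"), asg$well)],
               c("a", "b", "a", "b"))

  p96 <- plate_spec("96-medium")
  m96 <- alternating_map(p96, "buffer", "fluorescein")
  expect_equal(sum(m96$assignments$fluid == "buffer"), 48)
  expect_equal(sum(m96$assignments$fluid == "fluorescein"), 48)
  # every consecutive pair along the order switches fluid
  fl <- m96$assignments$fluid[match(m96$order, m96$assignments$well)]
  expect_equal(sum(fl[-96] != fl[-1]), 95)
  expect_equal(count_fluid_switches(m96, "buffer", "fluorescein"), 48)

  expect_error(alternating_map(p22, "a", "b", order = character(0)), "empty")
  expect_error(alternating_map(p22, "a", "b", order = c("A1", "A2")), "cover")

  m1 <- alternating_map(tiny_plate(1, 1), "a", "b")
  expect_equal(m1$assignments$fluid, "a")
})

test_that("carryover assay map yields exactly 48 dye-to-water switches on 96 wells", {
  m <- carryover_assay_map()
  expect_equal(count_fluid_switches(m, "fluorescein", "water"), 48)
  expect_equal(m$assignments$fluid[m$assignments$well == "A1"], "fluorescein")
})

test_that("screen map interleaves controls and obeys the length formula", {
  m <- screen_map(default_solvents())
  expect_equal(length(m$order), 57)
  fl <- m$assignments$fluid
  expect_equal(sum(fl == "buffer"), 29)
  expect_equal(fl[1], "buffer")
  expect_equal(fl[length(fl)], "buffer")
  # every solvent well preceded by a control
  solvent_pos <- which(fl != "buffer")
  expect_true(all(fl[solvent_pos - 1] == "buffer"))

  expect_equal(length(screen_map("s1", concentrations = 1)$order), 3)
  expect_equal(length(screen_map(c("s1", "s2"))$order), 9)
  for (n in c(1, 3, 8, 14)) {
    expect_equal(length(screen_map(paste0("s", 1:n))$order), 4 * n + 1)
  }
  expect_error(screen_map(paste0("s", 1:48)), "does not fit")
  expect_error(screen_map(character(0)), "at least one")
})

test_that("dilution series is a strictly decreasing geometric sequence", {
  expect_equal(dilution_series(100, 2, 3), c(100, 50, 25))
  expect_equal(dilution_series(5, 10, 1), 5)
  d <- dilution_series(11.5e-3, 10, 7)
  expect_equal(length(d), 7)
  expect_equal(d[1], 11.5e-3)
  expect_equal(d[7], 11.5e-9)
  expect_true(all(diff(d) < 0))
  expect_error(dilution_series(0, 10, 3), "top")
  expect_error(dilution_series(1, 1, 3), "factor")
  expect_error(dilution_series(1, 2, 0), "n must")
})

test_that("plate maps round-trip through CSV", {
  m <- carryover_assay_map()
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_map(m, path)
  m2 <- read_plate_map(path)
  expect_equal(m2$assignments, m$assignments)
  expect_equal(m2$order, m$order)
})

test_that("plate spec enforces the supported geometry ranges", {
  expect_error(plate_spec("wrong"), "unknown plate format")
  expect_error(plate_spec(NULL, rows = 2, cols = 2, well_capacity_ul = 100,
                          well_depth_mm = 40), "5-30")
  expect_error(plate_spec(NULL, rows = 2, cols = 2, well_capacity_ul = -1),
               "well_capacity")
  expect_equal(plate_spec("384")$well_capacity_ul, 225)
  expect_equal(plate_spec("96-deep")$well_capacity_ul, 2000)
})
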