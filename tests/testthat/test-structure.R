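test_that("chain extraction keeps author numbering and drops other chains", {
  f <- withr::local_tempfile(fileext = ".pdb")
  a <- make_structure(fixture_spec(seed = 1, geometry = "pair", distance = 6),
                      chain = "A")
  b <- make_structure(fixture_spec(seed = 1, geometry = "isolated"), chain = "B",
                      serial_start = 100L)
  writeLines(c(setdiff(a, c("TER", "END")), b), f)
  mA <- read_structure(f, "A")
  mB <- read_structure(f, "B")
  expect_equal(nrow(mA$residues), 2L)
  expect_equal(nrow(mB$residues), 1L)
  expect_error(read_structure(f, "Z"), "chain 'Z' not found")
})

test_that("insertion codes are preserved and sequence numbering follows the chain", {
  model <- read_fixture_structure(fixture_spec(seed = 1, geometry = "insertion_coded"))
  expect_equal(model$residues$resno, c(27L, 27L, 28L))
  expect_equal(model$residues$ins, c("", "A", ""))
  expect_equal(model$residues$seq_pos, 1:3)
  expect_equal(structure_sequence(model), "AAA")
})

test_that("altloc atoms resolve to the highest occupancy, ties to A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       5.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BALA A   1       9.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  m <- read_structure(f, "A")
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x[m$atoms$elety == "N"], 5.0)    # occupancy 0.6 wins
  expect_equal(m$atoms$x[m$atoms$elety == "CA"], 1.0)   # tie -> altloc A
})

test_that("hydrogens and waters are excluded; nonstandard residues kept unscored", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  H   ALA A   1       0.500   0.000   0.000  1.00  0.00           H",
    "ATOM      3  CA  MSE A   2       3.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A  90      20.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  m <- read_structure(f, "A")
  expect_equal(nrow(m$atoms), 2L)                    # CA of ALA + CA of MSE
  expect_true(is.na(m$residues$aa[m$residues$resid == "MSE"]))
  expect_equal(structure_sequence(m), "A")
})

test_that("contact environment matches the engineered pair distances", {
  m4 <- read_fixture_structure(fixture_spec(seed = 1, geometry = "pair", distance = 4))
  e4 <- find_environment(m4, structure_site(m4, seq_pos = 1), radius = 5)
  expect_equal(nrow(e4$neighbors), 1L)
  expect_equal(e4$neighbors$dist, 4, tolerance = 0.01)
  m6 <- read_fixture_structure(fixture_spec(seed = 1, geometry = "pair", distance = 6))
  e6 <- find_environment(m6, structure_site(m6, seq_pos = 1), radius = 5)
  expect_equal(nrow(e6$neighbors), 0L)
  # an isolated residue has an empty environment
  mi <- read_fixture_structure(fixture_spec(seed = 1, geometry = "isolated"))
  expect_equal(nrow(find_environment(mi, structure_site(mi, seq_pos = 1))$neighbors), 0L)
})

test_that("contact detection agrees with a brute-force all-pairs scan", {
  withr::local_seed(123)
  for (rep in 1:20) {
    geom <- sample(c("pair", "buried", "insertion_coded"), 1)
    spec <- fixture_spec(seed = sample.int(1e6, 1), geometry = geom,
                         distance = runif(1, 3.2, 8), n_shell = sample(4:12, 1))
    m <- read_fixture_structure(spec)
    radius <- runif(1, 3, 7)
    for (k in seq_len(nrow(m$residues))) {
      site <- structure_site(m, resno = m$residues$resno[k],
                             ins = m$residues$ins[k])
      env <- find_environment(m, site, radius = radius)
      expect_setequal(env$neighbors$key,
                      brute_force_neighbors(m, site$key, radius))
    }
  }
})

test_that("the contact relation is symmetric", {
  m <- read_fixture_structure(fixture_spec(seed = 8, geometry = "buried",
                                           n_shell = 8))
  radius <- 5
  keys <- m$residues$key
  for (k in seq_along(keys)) {
    site <- m$residues[k, ]; class(site) <- c("ddg_structure_site", class(site))
    for (nb in find_environment(m, site, radius)$neighbors$key) {
      j <- which(keys == nb)
      other <- m$residues[j, ]; class(other) <- c("ddg_structure_site", class(other))
      expect_true(site$key %in% find_environment(m, other, radius)$neighbors$key)
    }
  }
})

test_that("relative accessibility separates exposed from buried and clamps", {
  mi <- read_fixture_structure(fixture_spec(seed = 1, geometry = "isolated"))
  acc_iso <- relative_accessibility(mi, structure_site(mi, seq_pos = 1))
  expect_gte(acc_iso, 0.8)
  expect_lte(acc_iso, 1)
  mb <- read_fixture_structure(fixture_spec(seed = 1, geometry = "buried",
                                            n_shell = 26))
  acc_buried <- relative_accessibility(mb, structure_site(mb, seq_pos = 1))
  expect_lt(acc_buried, 0.2)
  expect_gte(acc_buried, 0)
  expect_lt(acc_buried, acc_iso)     # monotone burial
})

test_that("burial is monotone in shell density on nested fixtures", {
  accs <- vapply(c(1L, 6L, 14L, 26L), function(n) {
    geom <- if (n == 1L) "isolated" else "buried"
    m <- read_fixture_structure(fixture_spec(seed = 1, geometry = geom,
                                             n_shell = n))
    relative_accessibility(m, structure_site(m, seq_pos = 1))
  }, 0)
  expect_true(all(diff(accs) <= 0))
})

test_that("spatial score: single lookup case, anti-symmetry, empty environment", {
  P <- load_table("bastolla_vendruscolo")
  m <- read_fixture_structure(fixture_spec(seed = 1, geometry = "pair",
                                           distance = 4))
  # give the neighbour position a one-hot G column
  prof <- profile_from_cols(list(c(A = 1), c(G = 1)), query = c("A", "A"))
  env <- find_environment(m, structure_site(m, seq_pos = 1), radius = 5)
  expect_equal(score_bastolla(prof, env, "A1W"), P["G", "W"] - P["G", "A"])
  expect_identical(score_bastolla(prof, env, "A1W") +
                     score_bastolla(prof, env, "W1A"), 0)
  mi <- read_fixture_structure(fixture_spec(seed = 1, geometry = "isolated"))
  env0 <- find_environment(mi, structure_site(mi, seq_pos = 1))
  expect_identical(score_bastolla(prof, env0, "A1W"), 0)
})

test_that("environment residues without a profile mapping are skipped with a warning", {
  m <- read_fixture_structure(fixture_spec(seed = 1, geometry = "pair",
                                           distance = 4))
  m$residues$seq_pos[2] <- NA_integer_            # simulate an unmapped neighbour
  prof <- onehot("A")
  env <- find_environment(m, structure_site(m, seq_pos = 1), radius = 5)
  expect_warning(s <- score_bastolla(prof, env, "A1W"), "skipped")
  expect_identical(s, 0)
})

test_that("chain-to-query mapping allows overhang and rejects mismatches", {
  m <- read_fixture_structure(fixture_spec(seed = 1, geometry = "insertion_coded"))
  mapped <- map_structure(m, "GGAAAGG")     # chain AAA inside a longer query
  expect_equal(mapped$residues$seq_pos, 3:5)
  expect_error(map_structure(m, "GGGGG"), "does not match")
  # ambiguous placement is refused
  expect_error(map_structure(m, "AAAWAAA"), "exactly one offset")
})
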