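test_that("MACCS fingerprints match the key-definition oracle on probe molecules", {
  # expected on-keys frozen from the independent key-definition oracle
  # (aromatic ring = 162, six-ring = 163, any ring = 165 for benzene)
  fp <- maccs_fingerprint(c(benzene = "c1ccccc1", methane = "C"))
  expect_equal(which(fp["benzene", ] == 1), c(K162 = 162, K163 = 163, K165 = 165))
  # methane: only the trivial CH3 key fires
  expect_lte(sum(fp["methane", ]), 1)
  expect_equal(dim(fp), c(2L, 166L))
  expect_true(all(fp %in% c(0L, 1L)))
})

test_that("different SMILES spellings of one molecule give identical fingerprints", {
  for (pair in list(c("OCC", "CCO"), c("c1ccccc1C", "Cc1ccccc1"),
                    c("O=C(C)NC", "CNC(C)=O"))) {
    cleaned <- clean_structure(pair)
    fp <- maccs_fingerprint(cleaned)
    expect_equal(unclass(fp)[1, ], unclass(fp)[2, ], ignore_attr = TRUE)
  }
})

test_that("key selection keeps keys present in strictly more than min_count compounds", {
  # 50 compounds; key A in 6, key B in exactly 5, key C in none
  bits <- matrix(0L, nrow = 50, ncol = 166)
  bits[1:6, 10] <- 1L
  bits[1:5, 20] <- 1L
  bits[, 30] <- 0L
  bits[, 1] <- 1L  # keep at least one universal key
  fp <- fingerprint_matrix(bits)
  keys <- select_frequent_keys(fp, min_count = 5)
  expect_true(10 %in% keys)
  expect_false(20 %in% keys)
  expect_false(30 %in% keys)
  # monotone: raising min_count never adds keys
  for (m in c(0, 3, 7, 20)) {
    expect_true(all(select_frequent_keys(fp, m + 1) %in%
                      select_frequent_keys(fp, m)))
  }
  expect_error(select_frequent_keys(fp[0, , drop = FALSE], 5),
               class = "herbiscreen_validation_error")
})

test_that("physicochemical profile matches atom-count oracles on small molecules", {
  d <- physchem_profile(c("CCO", "c1ccccc1"))
  # ethanol: 1 OH donor, 1 O acceptor, 2 carbons, positive TPSA
  expect_equal(d$HBD[1], 1L)
  expect_equal(d$HBA[1], 1L)
  expect_equal(d$Cat[1], 2L)
  expect_gt(d$TPSA[1], 0)
  # benzene: no polar atoms at all
  expect_equal(d$HBD[2], 0L)
  expect_equal(d$TPSA[2], 0)
  expect_equal(d$RelPSA[2], 0)
  expect_true(all(d$RelPSA >= 0 & d$RelPSA <= 1))
  expect_true(all(d$MW > 0))
})

test_that("SMARTS counting agrees with hand atom counts on a 20-molecule panel", {
  panel <- data.frame(
    smiles = c("C", "CC", "CCC", "CCO", "CCN", "CC(=O)O", "c1ccccc1",
               "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1", "CC(=O)N", "CCOCC",
               "CS(=O)(=O)N", "C#N", "OCC(O)CO", "c1ccncc1", "CC(C)C",
               "ClCCl", "FC(F)F", "O=C(O)c1ccccc1"),
    HBD = c(0, 0, 0, 1, 1, 1, 0, 0, 1, 1, 1, 0, 1, 0, 3, 0, 0, 0, 0, 1),
    HBA = c(0, 0, 0, 1, 1, 2, 0, 0, 1, 1, 2, 1, 3, 1, 3, 1, 0, 0, 0, 2),
    Cat = c(1, 2, 3, 2, 2, 2, 6, 7, 6, 6, 2, 4, 1, 1, 3, 5, 4, 1, 1, 7))
  d <- physchem_profile(panel$smiles)
  expect_equal(d$HBD, as.integer(panel$HBD))
  expect_equal(d$HBA, as.integer(panel$HBA))
  expect_equal(d$Cat, as.integer(panel$Cat))
})

test_that("descriptor overrides win over computed values; unknown names error", {
  d <- physchem_profile("CCO", overrides = list(clogP = 2.5))
  expect_equal(d$clogP, 2.5)
  expect_true("clogP" %in% attr(d, "external"))
  expect_error(physchem_profile("CCO", overrides = list(bogus = 1)),
               class = "herbiscreen_config_error")
})

test_that("net-charge rules: acids negative, amines positive, hydrocarbons zero", {
  expect_equal(net_charge_estimate("CC(=O)O"), -1L)     # acetic acid
  expect_equal(net_charge_estimate("CCN"), 1L)          # ethylamine
  expect_equal(net_charge_estimate("c1ccccc1"), 0L)
  expect_equal(net_charge_estimate("CS(=O)(=O)O"), -1L) # methanesulfonic
  # any neutral hydrocarbon scores 0
  hydrocarbons <- c("C", "CCC", "c1ccccc1", "C1CCCCC1", "CC(C)C",
                    "c1ccc2ccccc2c1", "C=C", "C#C")
  expect_true(all(net_charge_estimate(hydrocarbons) == 0L))
})

test_that("Hayduk-Laudie diffusion: reference value, monotonicity, domain errors", {
  # V = 100 cm^3/mol in water at 25 C -> D ~ 1.0e-5 cm^2/s, logDiff ~ 0
  expect_equal(hayduk_laudie_log_diffusion(100, 0.8904), 0, tolerance = 0.01)
  # doubling the molar volume strictly decreases D
  v <- c(50, 100, 200, 400)
  ld <- hayduk_laudie_log_diffusion(v)
  expect_true(all(diff(ld) < 0))
  expect_error(hayduk_laudie_log_diffusion(0), class = "herbiscreen_domain_error")
  expect_error(hayduk_laudie_log_diffusion(100, -1),
               class = "herbiscreen_domain_error")
})

test_that("LeBas molar volume reproduces the benzene reference value", {
  # 6 C (14.8) + 6 H (3.7) - one six-ring deduction (15) = 96 cm^3/mol
  expect_equal(lebas_molar_volume("c1ccccc1"), 96, tolerance = 1e-9)
})

test_that("column scaling: exact small cases and training-stats reuse", {
  r <- scale_columns(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.numeric(r$scaled), c(-1, 0, 1))
  # applying training stats (mean 2, sd 1) to a new value 4 gives 2
  r2 <- scale_columns(matrix(4, ncol = 1, dimnames = list(NULL, "V1")),
                      stats = r$stats)
  expect_equal(as.numeric(r2$scaled), 2)
  expect_error(scale_columns(matrix(c(5, 5, 5), ncol = 1)),
               class = "herbiscreen_validation_error", regexp = "V1")
})

test_that("scaled training matrices have mean 0 and sample sd 1 per column", {
  set.seed(42)
  x <- matrix(rnorm(200, mean = 3, sd = 7), ncol = 4)
  sc <- scale_columns(x)$scaled
  expect_equal(colMeans(sc), rep(0, 4), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(apply(sc, 2, sd), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
})
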