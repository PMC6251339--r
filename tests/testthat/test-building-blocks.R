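# Precursor classification, database filtering, similarity and descriptors.

test_that("reactive-group classification counts aldehydes and amines", {
  tfb <- classify_topicity("O=Cc1cc(C=O)cc(C=O)c1")   # triformylbenzene
  expect_equal(tfb$group, "aldehyde")
  expect_equal(tfb$count, 3L)

  eda <- classify_topicity("NCCN")                     # ethane-1,2-diamine
  expect_equal(eda$group, "primary_amine")
  expect_equal(eda$count, 2L)

  # an amide nitrogen cannot condense to an imine and must not count
  expect_equal(classify_topicity("CC(N)=O"),
               list(group = "none", count = 0L))

  expect_error(classify_topicity("C1CC"), "unparseable")
})

test_that("database filter drops charged, metal-bearing and off-topicity molecules", {
  raw <- c("O=Cc1cc(C=O)cc(C=O)c1",      # keep: tri-topic aldehyde
           "NCCN",                        # keep: di-topic amine
           "[Na+].[O-]C(=O)c1ccccc1",     # drop: charged + metal
           "CC(N)=O",                     # drop: amide, not amine
           "NCCCN",                       # keep
           "O=CCC=O")                     # drop: di-topic aldehyde
  db <- filter_database(raw, embed = FALSE)
  expect_s3_class(db, "bb_database")
  expect_equal(length(db), 3L)
  rep <- attr(db, "removed")
  expect_true(sum(rep$n) == 3L)
  expect_true(rep$n[rep$rule == "wrong_topicity"] >= 2L)

  # canonical dedup: two spellings of the same diamine collapse to one member
  sp <- c("NCCN", "C(CN)N")
  expect_equal(canonical_smiles(sp[1]), canonical_smiles(sp[2]))
  db2 <- filter_database(sp, embed = FALSE)
  expect_equal(length(db2), 1L)

  expect_warning(filter_database("CC(N)=O", embed = FALSE), "empty")
})

test_that("filter output is invariant to input ordering and SMILES spelling", {
  raw1 <- c("O=Cc1cc(C=O)cc(C=O)c1", "NCCN", "NCCCN")
  raw2 <- c("C(CN)N", "NCCCN", "O=Cc1cc(C=O)cc(C=O)c1")  # reordered/respelled
  db1 <- filter_database(raw1, embed = FALSE)
  db2 <- filter_database(raw2, embed = FALSE)
  smi <- function(db) sort(vapply(db$members, `[[`, character(1), "smiles"))
  expect_equal(smi(db1), smi(db2))
})

test_that("Dice similarity matches the set formula and is a bounded symmetric measure", {
  bz <- building_block("c1ccccc1C=O", "bz")
  tfb <- building_block("O=Cc1cc(C=O)cc(C=O)c1", "tfb")
  # direct set-formula oracle on the raw bit vectors
  expect_equal(dice_similarity(bz, tfb),
               dice_oracle(bz$fingerprint, tfb$fingerprint))
  expect_equal(dice_similarity(bz, bz), 1.0)

  a <- structure(c(1L, 1L, 0L, 0L), nbits = 4L, radius = 1L)
  b <- structure(c(0L, 0L, 1L, 1L), nbits = 4L, radius = 1L)
  expect_equal(dice_similarity(a, b), 0)

  set.seed(42)
  for (i in 1:100) {
    fa <- random_fp(sample(5:80, 1)); fb <- random_fp(sample(5:80, 1))
    s1 <- dice_similarity(fa, fb); s2 <- dice_similarity(fb, fa)
    expect_identical(s1, s2)
    expect_gte(s1, 0); expect_lte(s1, 1)
    expect_equal(s1, dice_oracle(fa, fb))
  }
  expect_equal(dice_similarity(random_fp(30), structure(
    integer(2048), nbits = 2048L, radius = 1L)), 0)

  bad <- structure(integer(1024), nbits = 1024L, radius = 1L)
  expect_error(dice_similarity(random_fp(10), bad), "parameters")
})

test_that("similarity ranking follows the brute-force Dice order with id tie-breaks", {
  db <- test_db_flat(5L, 30L)
  di_ids <- evocage:::db_ids(db, "diamine")
  target <- db$members[[di_ids[1]]]
  others <- setdiff(di_ids, target$id)
  sims <- vapply(others, function(i) dice_similarity(target, db$members[[i]]),
                 numeric(1))
  expected_order <- others[order(-sims, others)]
  got <- vapply(seq_along(others), function(n)
    similarity_rank(target, db, n)$id, character(1))
  expect_identical(got, expected_order)
  # ranked members are distinct and similarity is non-increasing
  expect_equal(anyDuplicated(got), 0L)
  expect_true(all(diff(sims[match(got, others)]) <= 1e-12))
  expect_error(similarity_rank(target, db, length(others) + 1L), "exceeds")
})

test_that("chain-length neighbors rank closer than distant ones", {
  raw <- c("NCCN", "NCCCCN", "NCCCCCCCCN")
  db <- filter_database(raw, ids = c("c2", "c4", "c8"), embed = FALSE)
  target <- db$members[["c2"]]
  expect_identical(similarity_rank(target, db, 1)$id, "c4")
  expect_identical(similarity_rank(target, db, 2)$id, "c8")
})

test_that("descriptors report bond percentages and anchor distances", {
  db <- test_db()
  di <- db$members[[first_id(db, "diamine")]]
  d <- bb_descriptors(di)
  expect_gte(d$pct_rotatable, 0); expect_lte(d$pct_rotatable, 100)
  expect_gte(d$pct_double, 0); expect_lte(d$pct_double, 100)

  # cross-check the N-N distance by direct coordinate arithmetic
  anchors <- evocage:::find_anchor_atoms(di$conformer, "diamine")
  expect_length(anchors, 2L)
  dd <- sqrt(sum((di$conformer$coords[anchors[1], ] -
                    di$conformer$coords[anchors[2], ])^2))
  expect_equal(d$end_group_distance, dd)

  # a 1,2-diamine has the signature ~3.5 A (wide tolerance: single conformer)
  eda <- embed_3d(building_block("NCCN", "eda"), seed = 5)
  d_eda <- bb_descriptors(eda)
  expect_gt(d_eda$end_group_distance, 2.5)
  expect_lt(d_eda$end_group_distance, 4.2)

  # benzene has no rotatable bonds
  expect_equal(evocage:::bond_stats("c1ccccc1")[[1]]$n_rotatable, 0L)
})

test_that("ETKDG embedding is seed-deterministic with sane geometry", {
  c1 <- embed_smiles("NC1CCCCC1N", seed = 9)[[1]]
  c2 <- embed_smiles("NC1CCCCC1N", seed = 9)[[1]]
  expect_identical(c1, c2)
  d <- evocage:::bonded_distances(c1)
  expect_true(all(d > 0.7 & d < 1.9))

  w <- embed_smiles("O", seed = 3)[[1]]
  expect_length(w$elements, 3L)
  oh <- evocage:::bonded_distances(w)
  expect_true(all(abs(oh - 0.96) < 0.1))

  # both amine nitrogens survive into the conformer
  eda <- embed_smiles("NCCN", seed = 4)[[1]]
  expect_equal(sum(eda$elements == "N"), 2L)
})

test_that("database io round-trips members and reports removals", {
  db <- test_db_flat(3L, 5L, seed = 2L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_bb_database(db, tsv)
  back <- read_smiles_file(tsv)
  expect_equal(nrow(back), length(db))
  expect_setequal(back$id, names(db$members))

  raw <- c("NCCN", "bogus(((", "NCCN")
  db2 <- filter_database(raw, embed = FALSE)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_filter_report(db2, csv)
  rep <- read.csv(csv)
  expect_equal(rep$n[rep$rule == "unparseable"], 1L)
  expect_equal(rep$n[rep$rule == "duplicate"], 1L)
})
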