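test_that("haplotype-table tokens parse into the expected variant calls", {
  tmp <- withr_local_tempfile()
  writeLines(c("S1\t73G 16519C", "S2"), tmp)
  meta <- withr_local_tempfile()
  writeLines(c("id,age_bp,haplogroup,macrohaplogroup",
               "S1,-50,H1,R", "S2,-50,H1,R"), meta)
  profs <- read_profiles(tmp, meta, reference = ref, format = "table")
  expect_length(profs, 2)
  v <- profs[["S1"]]$variants
  expect_equal(nrow(v), 2)
  expect_equal(v$position, c(73L, 16519L))
  expect_true(all(v$kind == "substitution"))
  expect_equal(nrow(profs[["S2"]]$variants), 0)
})

test_that("aligned FASTA calls variants column-wise against the reference", {
  identical_seq <- paste(ref$bases, collapse = "")
  mutated <- ref$bases
  mutated[100] <- setdiff(c("A", "C", "G", "T"), ref$bases[100])[1]
  mutated[5000:5002] <- "-"         # a 3-bp gap run
  fa <- withr_local_tempfile(ext = ".fasta")
  writeLines(c(">A", identical_seq, ">B", paste(mutated, collapse = "")), fa)
  meta <- withr_local_tempfile()
  writeLines(c("id,age_bp,haplogroup,macrohaplogroup",
               "A,-50,H,R", "B,-50,H,R"), meta)
  profs <- read_profiles(fa, meta, reference = ref)
  expect_equal(nrow(profs[["A"]]$variants), 0)
  vb <- profs[["B"]]$variants
  expect_equal(nrow(vb), 2)         # one substitution + one deletion run
  del <- vb[vb$kind == "deletion", ]
  expect_equal(del$position, 5000L) # recorded at its first position
  expect_equal(nchar(del$ref), 3L)
})

test_that("sequences with the wrong alignment length are rejected by name", {
  fa <- withr_local_tempfile(ext = ".fasta")
  writeLines(c(">ok", paste(ref$bases, collapse = ""),
               ">short", paste(ref$bases[-1], collapse = "")), fa)
  meta <- withr_local_tempfile()
  writeLines(c("id,age_bp,haplogroup,macrohaplogroup",
               "ok,-50,H,R", "short,-50,H,R"), meta)
  expect_error(read_profiles(fa, meta, reference = ref), "short")
})

test_that("metadata and sequence ids must match one-to-one", {
  tmp <- withr_local_tempfile()
  writeLines("S1\t73G", tmp)
  meta <- withr_local_tempfile()
  writeLines(c("id,age_bp,haplogroup,macrohaplogroup", "S9,-50,H,R"), meta)
  expect_error(read_profiles(tmp, meta, reference = ref, format = "table"),
               "S1")
})

test_that("exclusion policy drops window indels and all 16519 calls", {
  policy <- exclusion_policy()
  p <- mito_profile("x", -50, "H", "R", variant_table(
    position = c(309L, 73L),
    ref = c("-", ref$bases[73]),
    alt = c("C", setdiff(c("A", "C", "G", "T"), ref$bases[73])[1]),
    kind = c("insertion", "substitution")))
  filtered <- apply_exclusions(p, policy)
  expect_equal(filtered$variants$position, 73L)

  hotspot <- sub_profile("y", 16519)
  expect_equal(nrow(apply_exclusions(hotspot, policy)$variants), 0)

  # substitutions inside an indel window are kept
  sub_in_window <- sub_profile("z", 310)
  expect_equal(nrow(apply_exclusions(sub_in_window, policy)$variants), 1)

  # untouched profile passes through, and filtering is idempotent
  clean <- sub_profile("w", c(73, 263))
  expect_identical(apply_exclusions(clean, policy)$variants, clean$variants)
  expect_identical(apply_exclusions(apply_exclusions(p, policy), policy),
                   apply_exclusions(p, policy))
})

test_that("pair differences count the filtered symmetric difference", {
  a <- sub_profile("a", 73)
  b <- sub_profile("b", c(73, 150))
  expect_equal(pair_difference(a, a), 0)
  expect_equal(pair_difference(a, b), 1)
  expect_equal(pair_difference(b, a), 1)

  # 16519 is excluded; 73 and 263 are each private to one profile
  c1 <- sub_profile("c1", c(73, 16519))
  c2 <- sub_profile("c2", c(16519, 263))
  expect_equal(pair_difference(c1, c2), 2)
})

test_that("pair difference behaves as a symmetric-difference metric", {
  set.seed(99)
  pool <- c(1:300, 400:700)
  profs <- lapply(1:12, function(i) {
    sub_profile(paste0("p", i), sample(pool, sample(0:8, 1)))
  })
  for (i in 1:12) {
    expect_equal(pair_difference(profs[[i]], profs[[i]]), 0)
  }
  for (rep in 1:30) {
    idx <- sample(12, 3)
    dab <- pair_difference(profs[[idx[1]]], profs[[idx[2]]])
    dba <- pair_difference(profs[[idx[2]]], profs[[idx[1]]])
    dac <- pair_difference(profs[[idx[1]]], profs[[idx[3]]])
    dcb <- pair_difference(profs[[idx[3]]], profs[[idx[2]]])
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb)
  }
})

test_that("profiles round-trip through the haplotype-table dialect", {
  profs <- list(sub_profile("r1", c(73, 263, 750)),
                sub_profile("r2", integer()),
                mito_profile("r3", 1200, "U5a", "R", variant_table(
                  position = c(522L, 8280L),
                  ref = c(paste0(ref$bases[522:523], collapse = ""), "-"),
                  alt = c("-", "AC"),
                  kind = c("deletion", "insertion"))))
  tab <- withr_local_tempfile()
  meta <- withr_local_tempfile()
  write_haplotype_table(profs, tab)
  writeLines(c("id,age_bp,haplogroup,macrohaplogroup",
               "r1,-50,H,R", "r2,-50,H,R", "r3,1200,U5a,R"), meta)
  back <- read_profiles(tab, meta, reference = ref, format = "table")
  expect_equal(variant_keys(back[["r1"]]), variant_keys(profs[[1]]))
  expect_equal(variant_keys(back[["r2"]]), character())
  expect_setequal(variant_keys(back[["r3"]]), variant_keys(profs[[3]]))
})

test_that("variant invariants are enforced", {
  expect_error(variant_table(0, "A", "G"), "positions")
  expect_error(variant_table(20000, "A", "G"), "positions")
  expect_error(variant_table(73, "A", "A"), "differ")
  expect_error(mito_profile("x", -80, "H", "R"), "age_bp")
  expect_error(mito_profile("x", -50, "H", "X"), "macrohaplogroup")
})
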