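mini_alignment <- function() {
  aligned_set(c(ref  = "AC-DEFGH",
                s1   = "ACWDEFGH",
                s2   = "ACWDEYGH",
                s3   = "AC-DEFGH",
                frag = "----EFGH"), "ref")
}

test_that("reference positions map through gaps", {
  a <- aligned_set(c(ref = "AC-DE", x = "ACWDE"), "ref")
  expect_equal(map_reference_position(a, 3), 4L)
  expect_equal(map_reference_position(a, 1), 1L)
  expect_error(map_reference_position(a, 8), "outside")

  # brute-force scan oracle on a random gappy reference
  set.seed(21)
  chars <- sample(c("A", "R", "N", "-"), 60, replace = TRUE, prob = c(3, 3, 3, 2))
  gappy <- aligned_set(c(ref = paste(chars, collapse = ""),
                         other = paste(rep("A", 60), collapse = "")), "ref")
  resno <- 0
  for (col in seq_along(chars)) {
    if (chars[col] == "-") next
    resno <- resno + 1
    expect_equal(map_reference_position(gappy, resno), col)
  }
})

test_that("redundancy filtering drops duplicates and fragments, keeps reference", {
  a <- mini_alignment()
  f <- filter_redundancy(a)
  expect_setequal(names(f$records), c("ref", "s1", "s2"))  # s3 duplicates ref
  # idempotent
  expect_equal(filter_redundancy(f), f)

  # reference retained even when a duplicate precedes it alphabetically
  dup_first <- aligned_set(c(zz = "ACDE", ref = "ACDE", other = "AQDE"), "ref")
  f2 <- filter_redundancy(dup_first)
  expect_true("ref" %in% names(f2$records))
  expect_false("zz" %in% names(f2$records))

  # synthetic bookkeeping: 6 base + 3 duplicates + 1 fragment -> 6 retained
  gen <- gen_alignment(n_sequences = 6, compositions = list(`10` = c(D = 1)),
                       n_duplicates = 3, n_fragments = 1, seed = 2,
                       ref_length = 40)
  expect_length(gen$alignment$records, 10L)
  kept <- filter_redundancy(gen$alignment)
  expect_length(kept$records, 6L)
  expect_false(any(gen$truth$duplicate_ids %in% names(kept$records)))
  expect_false(any(gen$truth$fragment_ids %in% names(kept$records)))
})

test_that("column frequencies count residues and gaps correctly", {
  a <- aligned_set(c(ref = paste(rep("A", 10), collapse = ""),
                     setNames(c(rep("ADAAAAAAAA", 6), rep("AEAAAAAAAA", 3),
                                "A-AAAAAAAA"), paste0("s", 1:10))), "ref")
  prof <- column_frequencies(a, 2)
  expect_equal(prof$n_gap, 1L)
  expect_equal(sum(prof$percent), 100)
  expect_equal(prof$percent[prof$residue == "D"], 60)
  expect_equal(prof$percent[prof$residue == "E"], 30)
  # percentages plus gaps account for every record
  expect_equal(sum(prof$count) + prof$n_gap, prof$n_sequences)

  single <- aligned_set(c(ref = "FF", a = "FF", b = "FF"), "ref")
  p1 <- column_frequencies(single, 1)
  expect_equal(p1$percent, 100)

  gapcol <- aligned_set(c(ref = "A-B", x = "A-B"), "ref")
  expect_error(column_frequencies(gapcol, 2), NA)  # position 2 maps past gap
})

test_that("profiles are invariant to record order and all-gap columns", {
  gen <- gen_alignment(n_sequences = 40, seed = 3, ref_length = 470)
  a <- gen$alignment
  prof <- pocket_profile(a)
  expect_length(prof, 7L)

  set.seed(4)
  shuffled_ids <- c(a$reference_id,
                    sample(setdiff(names(a$records), a$reference_id)))
  b <- aligned_set(a$records[shuffled_ids], a$reference_id)
  prof_b <- pocket_profile(b)
  for (i in seq_along(prof)) {
    expect_equal(prof_b[[i]]$percent, prof[[i]]$percent)
    expect_equal(prof_b[[i]]$residue, prof[[i]]$residue)
  }

  # inserting an all-gap column upstream shifts nothing in reference numbering
  with_gap <- vapply(a$records, function(s)
    paste0(substr(s, 1, 100), "-", substr(s, 101, nchar(s))), "")
  cprof <- pocket_profile(aligned_set(with_gap, a$reference_id))
  for (i in seq_along(prof))
    expect_equal(cprof[[i]]$percent, prof[[i]]$percent)
})

test_that("ambiguity handling flag controls the denominator", {
  a <- aligned_set(c(ref = "D", s1 = "D", s2 = "X", s3 = "E"), "ref")
  incl <- column_frequencies(a, 1)
  expect_equal(incl$percent[incl$residue == "D"], 50)
  excl <- column_frequencies(a, 1, exclude_ambiguous = TRUE)
  expect_equal(excl$percent[excl$residue == "D"], 100 * 2 / 3)
})

test_that("profile tables flatten in position order", {
  gen <- gen_alignment(n_sequences = 20, seed = 6, ref_length = 470)
  tab <- profile_table(pocket_profile(gen$alignment, c(395, 404)))
  expect_equal(unique(tab$position), c(395, 404))
  expect_true(all(c("position", "residue", "percent", "count") %in% names(tab)))
})
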