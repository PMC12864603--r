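test_that("validate_peptides enforces alphabet, length and labels", {
  ok <- validate_peptides(data.frame(sequence = c("acDK", "GG"),
                                     label = c(1, 0)))
  expect_s3_class(ok, "tbl_df")
  expect_identical(ok$sequence, c("ACDK", "GG"))
  expect_identical(ok$label, c(1L, 0L))

  expect_error(validate_peptides(data.frame(sequence = "ACXZ")),
               class = "aopred_validation_error")
  err <- tryCatch(validate_peptides(
    data.frame(id = "bad1", sequence = "ABBA")), error = identity)
  expect_match(conditionMessage(err), "bad1")

  expect_error(validate_peptides(data.frame(sequence = "A")),
               class = "aopred_validation_error")
  long <- paste(rep("A", 60), collapse = "")
  expect_error(validate_peptides(data.frame(sequence = long)),
               class = "aopred_validation_error")
  expect_message(
    tr <- validate_peptides(data.frame(sequence = long), truncate = TRUE),
    "Truncating"
  )
  expect_identical(nchar(tr$sequence), 50L)

  expect_error(validate_peptides(data.frame(sequence = "GG", label = 2)),
               class = "aopred_validation_error")
  expect_error(
    validate_peptides(data.frame(id = c("a", "a"), sequence = c("GG", "GA"))),
    class = "aopred_validation_error"
  )
})

test_that("FASTA and table round-trips preserve records exactly", {
  man <- tiny_manifest(5, 5, seed = 2)
  fa <- withr::local_tempfile(fileext = ".fasta")
  csv <- withr::local_tempfile(fileext = ".csv")

  write_peptide_fasta(man, fa)
  back <- read_peptide_fasta(fa)
  expect_identical(back$id, man$id)
  expect_identical(back$sequence, man$sequence)
  expect_identical(back$label, man$label)

  write_peptide_table(man, csv)
  back2 <- read_peptide_table(csv)
  expect_identical(back2$id, man$id)
  expect_identical(back2$sequence, man$sequence)
  expect_identical(back2$label, man$label)
})

test_that("read_peptide_fasta rejects malformed files and bad labels", {
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("GGAC", ">p1 label=1", "GG"), bad)
  err <- tryCatch(read_peptide_fasta(bad), error = identity)
  expect_s3_class(err, "aopred_parse_error")
  expect_match(conditionMessage(err), "line 1")

  bad2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 label=7", "GG"), bad2)
  expect_error(read_peptide_fasta(bad2), class = "aopred_validation_error")

  missing_label <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "GG", ">p2 label=1", "ACD"), missing_label)
  m <- read_peptide_fasta(missing_label)
  expect_identical(m$label, c(NA_integer_, 1L))
})

test_that("read_peptide_table sniffs delimiters and custom columns", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pep\ty", "GGA\t1", "ACD\t0"), tsv)
  m <- read_peptide_table(tsv, seq_col = "pep", label_col = "y")
  expect_identical(m$sequence, c("GGA", "ACD"))
  expect_identical(m$label, c(1L, 0L))
  expect_identical(m$id, c("1", "2"))

  semi <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id;sequence;label", "x;GG;1"), semi)
  m2 <- read_peptide_table(semi)
  expect_identical(m2$sequence, "GG")

  expect_error(read_peptide_table(tsv, seq_col = "nope"),
               class = "aopred_config_error")
  expect_error(read_peptide_table("no/such/file.csv"),
               class = "aopred_io_error")
})

test_that("merge_datasets handles ids, duplicates and conflicts", {
  a <- validate_peptides(
    data.frame(id = c("p1", "p2"), sequence = c("GGA", "ACD"),
               label = c(1, 0)), name = "a")
  b <- validate_peptides(
    data.frame(id = c("p1", "p3"), sequence = c("GGA", "WYH"),
               label = c(0, 1)), name = "b")

  plain <- merge_datasets(list(a, b))
  expect_identical(nrow(plain), 4L)
  expect_false(anyDuplicated(plain$id) > 0)

  expect_warning(ded <- merge_datasets(list(a, b), deduplicate = TRUE),
                 "conflict")
  expect_identical(nrow(ded), 3L)
  expect_identical(ded$label[ded$sequence == "GGA"], 1L) # first wins

  expect_warning(
    drop <- merge_datasets(list(a, b), deduplicate = TRUE,
                           drop_conflicts = TRUE),
    "conflict"
  )
  expect_false("GGA" %in% drop$sequence)

  # idempotence of deduplicating merge
  again <- merge_datasets(drop, deduplicate = TRUE)
  expect_identical(again$sequence, drop$sequence)
})

test_that("make_folds is deterministic, stratified and balanced", {
  man <- generate_peptides(synth_spec(53, 47, seed = 9))
  f1 <- make_folds(man, k = 5, seed = 4)
  f2 <- make_folds(man, k = 5, seed = 4)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:5)

  sizes <- tabulate(f1, 5)
  expect_lte(max(sizes) - min(sizes), 1L)
  for (cls in 0:1) {
    per <- tabulate(f1[man$label == cls], 5)
    expect_lte(max(per) - min(per), 1L)
  }
  # union = all records, pairwise disjoint is implied by a single assignment
  expect_identical(length(f1), nrow(man))

  expect_error(make_folds(man, k = 1), class = "aopred_config_error")
  expect_error(make_folds(man, k = 101), class = "aopred_config_error")
  man$label[1] <- NA
  expect_error(make_folds(man, k = 5), class = "aopred_config_error")
})

test_that("split_by_length partitions every input", {
  man <- tiny_manifest(10, 10, seed = 3, max_len = 30)
  for (thr in c(1, 5, 15, 51)) {
    parts <- split_by_length(man, threshold = thr)
    expect_identical(nrow(parts$short) + nrow(parts$long), nrow(man))
    if (nrow(parts$short)) expect_true(all(nchar(parts$short$sequence) < thr))
    if (nrow(parts$long)) expect_true(all(nchar(parts$long$sequence) >= thr))
  }
})

test_that("pairwise_identity matches hand-computed alignments", {
  q <- validate_peptides(data.frame(id = "q", sequence = "GGG"))
  r <- validate_peptides(data.frame(id = c("r1", "r2"),
                                    sequence = c("GGG", "AAA")))
  out <- pairwise_identity(q, r)
  expect_equal(out$identity, 100)

  # query GG vs reference AA: alignment has no matches
  out2 <- pairwise_identity(
    validate_peptides(data.frame(sequence = "GG")),
    validate_peptides(data.frame(sequence = "AA"))
  )
  expect_equal(out2$identity, 0)

  # GGA vs GG: two matches over three alignment columns
  out3 <- pairwise_identity(
    validate_peptides(data.frame(sequence = "GGA")),
    validate_peptides(data.frame(sequence = "GG"))
  )
  expect_equal(out3$identity, 100 * 2 / 3)
  expect_equal(attr(out3, "mean_identity"), 100 * 2 / 3)
})
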