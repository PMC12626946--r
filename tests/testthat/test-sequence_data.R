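test_that("reading the native TSV pairs chains into validated complexes", {
  ds <- read_chain_table(write_tiny_tsv())
  expect_s3_class(ds, "labeled_dataset")
  expect_length(ds, 2L)
  cx <- ds$complexes[[1]]
  expect_identical(cx$heavy$sequence, "ACDE")
  expect_identical(cx$heavy$labels, c(0L, 1L, 0L, 0L))
  expect_identical(cx$light$chain_type, "L")
  expect_identical(cx$heavy$complex_id, cx$light$complex_id)
})

test_that("malformed records fail hard, naming the offending complex", {
  path <- tempfile(fileext = ".tsv")
  tab <- data.frame(complex_id = "BAD1", chain_type = "H",
                    sequence = "ACDE", labels = "010")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_chain_table(path), "BAD1")
  expect_error(read_chain_table(tempfile()), "does not exist")
  expect_error(labeled_chain("Z", "H", "ACDE", "01a0"), "0/1")
})

test_that("complexes missing either chain are excluded with a report", {
  path <- tempfile(fileext = ".tsv")
  tab <- data.frame(complex_id = c("X1", "X1", "X2"),
                    chain_type = c("H", "L", "H"),
                    sequence = c("ACDE", "WYKL", "MNPQ"),
                    labels = c("0100", "1000", "0011"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(ds <- read_chain_table(path), "X2")
  expect_length(ds, 1L)
  expect_identical(attr(ds, "excluded"), "X2")
})

test_that("non-standard residues are normalized to X with a warning count", {
  expect_warning(
    ch <- build_dataset_from_records(data.frame(
      complex_id = c("N1", "N1"), chain_type = c("H", "L"),
      sequence = c("ACBZ", "UO*A"), labels = c("0000", "0000"))),
    "5 non-standard"
  )
  expect_identical(ch$complexes[[1]]$heavy$sequence, "ACXX")
  expect_identical(ch$complexes[[1]]$light$sequence, "XXXA")
})

test_that("fasta_pair input matches the equivalent TSV input", {
  skip_if_not_installed("Biostrings")
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">X1_H", "ACDE", ">X1_L", "WYKL"), fa)
  lab <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(id = c("X1_H", "X1_L"),
                                labels = c("0100", "1000")),
                     lab, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- read_chain_table(fa, format = "fasta_pair", label_path = lab)
  expect_length(ds, 1L)
  expect_identical(ds$complexes[[1]]$heavy$sequence, "ACDE")
  expect_identical(ds$complexes[[1]]$light$labels, c(1L, 0L, 0L, 0L))
})

test_that("length filter keeps a complex only when both chains are in bounds", {
  mk <- function(id, lh, ll) {
    antibody_complex(random_chain(id, "H", lh), random_chain(id, "L", ll))
  }
  ds <- labeled_dataset(list(mk("A", 115L, 108L), mk("B", 110L, 130L),
                             mk("C", 131L, 120L)))
  out <- filter_by_length(ds, 110L, 130L)
  expect_identical(vapply(out$complexes, `[[`, character(1), "complex_id"), "B")
  expect_identical(attr(out, "n_removed"), 2L)
  # idempotent and identity on empty
  again <- filter_by_length(out, 110L, 130L)
  expect_identical(lapply(again$complexes, `[[`, "complex_id"),
                   lapply(out$complexes, `[[`, "complex_id"))
  expect_length(filter_by_length(labeled_dataset(list()), 110L, 130L), 0L)
})

test_that("padding is right-aligned and mask counts the real residues", {
  ch <- random_chain("P1", "H", 112L)
  pc <- pad_and_mask(ch, 130L)
  expect_identical(pc$mask, c(rep(1L, 112L), rep(0L, 18L)))
  expect_identical(sum(pc$mask), chain_length(ch))
  expect_identical(pc$padded_labels[113:130], rep(0L, 18L))
  full <- pad_and_mask(random_chain("P2", "H", 130L), 130L)
  expect_identical(full$mask, rep(1L, 130L))
  expect_error(pad_and_mask(random_chain("P3", "H", 131L), 130L), "filter")
})

test_that("dataset summary counts unpadded residues and matches padding-free totals", {
  ds <- read_chain_table(write_tiny_tsv())
  s <- dataset_summary(ds)
  expect_identical(s$n_complexes, 2L)
  expect_identical(s$n_chains, 4L)
  expect_identical(s$n_residues, 16L)
  expect_identical(s$n_binding, 4L)
  expect_equal(s$binding_fraction, 0.25)
  expect_equal(s$per_chain_type$n_binding, c(3L, 1L))
  expect_error(dataset_summary(labeled_dataset(list())), "empty")
})

test_that("dataset TSV round-trip preserves sequences and labels exactly", {
  ds <- generate_worked_micro_example()
  path <- tempfile(fileext = ".tsv")
  write_chain_table(ds, path)
  back <- read_chain_table(path)
  expect_identical(lapply(all_chains(back), `[[`, "sequence"),
                   lapply(all_chains(ds), `[[`, "sequence"))
  expect_identical(lapply(all_chains(back), `[[`, "labels"),
                   lapply(all_chains(ds), `[[`, "labels"))
})

test_that("prediction TSV writing validates inputs and round-trips to 6 decimals", {
  rec <- list(list(complex_id = "X1", chain_type = "H", sequence = "ACDE",
                   probabilities = c(0.1, 0.923456, 0.5, 1), calls = c(0, 1, 1, 1)))
  path <- tempfile(fileext = ".tsv")
  write_predictions(rec, path)
  tab <- read_predictions(path)
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$position, 1:4)
  expect_identical(tab$residue, c("A", "C", "D", "E"))
  expect_equal(tab$probability, c(0.1, 0.923456, 0.5, 1), tolerance = 1e-6)
  bad <- rec
  bad[[1]]$probabilities[2] <- 1.5
  expect_error(write_predictions(bad, tempfile()), "\\[0,1\\]")
  short <- rec
  short[[1]]$probabilities <- c(0.1, 0.2)
  expect_error(write_predictions(short, tempfile()), "probabilities")
})
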