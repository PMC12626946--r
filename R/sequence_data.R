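#' @title Labeled antibody chains, complexes and datasets
#' @description Constructors and validators for the core data types:
#'   a `labeled_chain` is one variable-domain sequence with per-residue
#'   binary binding labels; an `antibody_complex` pairs the heavy (H) and
#'   light (L) chain of one antibody-antigen complex; a `labeled_dataset`
#'   is an ordered collection of complexes with free-text provenance.
#' @name sequence-data
NULL

#' Create a labeled antibody chain
#'
#' @param complex_id Complex identifier shared by both chains of an antibody.
#' @param chain_type `"H"` (heavy) or `"L"` (light).
#' @param sequence Amino-acid string; letters outside the 20 standard amino
#'   acids are normalized to `"X"` (a `normalized` attribute counts them).
#' @param labels Binary vector (or a string of `'0'`/`'1'` characters), one
#'   value per residue; 1 marks a binding (paratope) residue.
#' @return A `labeled_chain` object.
#' @export
labeled_chain <- function(complex_id, chain_type, sequence, labels) {
  stopifnot(is.character(complex_id), length(complex_id) == 1L, nzchar(complex_id))
  chain_type <- match.arg(chain_type, c("H", "L"))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.character(labels) && length(labels) == 1L) {
    lab_chr <- strsplit(labels, "")[[1]]
    if (!all(lab_chr %in% c("0", "1"))) {
      stop("labels string for complex '", complex_id, "' contains characters other than 0/1")
    }
    labels <- as.integer(lab_chr)
  }
  labels <- as.integer(labels)
  norm <- normalize_sequence(sequence)
  if (nchar(norm$sequence) != length(labels)) {
    stop("sequence/label length mismatch for complex '", complex_id, "' chain ",
         chain_type, ": ", nchar(norm$sequence), " residues vs ", length(labels), " labels")
  }
  if (length(labels) == 0L) stop("empty sequence for complex '", complex_id, "'")
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels for complex '", complex_id, "' must all be 0 or 1")
  }
  structure(
    list(complex_id = complex_id, chain_type = chain_type,
         sequence = norm$sequence, labels = labels),
    n_normalized = norm$n_normalized,
    class = "labeled_chain"
  )
}

# uppercase and map non-standard letters (B, Z, U, O, *, ...) to 'X'
normalize_sequence <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- !(chars %in% aa_standard()) & chars != "X"
  chars[bad] <- "X"
  list(sequence = paste(chars, collapse = ""), n_normalized = sum(bad))
}

#' @export
print.labeled_chain <- function(x, ...) {
  cat(sprintf("<labeled_chain> %s [%s] %d residues, %d binding\n",
              x$complex_id, x$chain_type, nchar(x$sequence), sum(x$labels)))
  invisible(x)
}

chain_length <- function(chain) nchar(chain$sequence)

#' Pair a heavy and a light chain into an antibody complex
#'
#' @param heavy,light `labeled_chain` objects of chain type H and L carrying
#'   the same complex identifier.
#' @return An `antibody_complex` object.
#' @export
antibody_complex <- function(heavy, light) {
  stopifnot(inherits(heavy, "labeled_chain"), inherits(light, "labeled_chain"))
  if (heavy$chain_type != "H") stop("'heavy' must have chain_type H")
  if (light$chain_type != "L") stop("'light' must have chain_type L")
  if (heavy$complex_id != light$complex_id) {
    stop("paired chains carry different complex ids: '", heavy$complex_id,
         "' vs '", light$complex_id, "'")
  }
  structure(list(complex_id = heavy$complex_id, heavy = heavy, light = light),
            class = "antibody_complex")
}

#' Build a labeled dataset from antibody complexes
#'
#' @param complexes List of `antibody_complex` objects with unique ids.
#' @param provenance Free-text metadata (source, filters applied).
#' @return A `labeled_dataset` object.
#' @export
labeled_dataset <- function(complexes, provenance = character()) {
  stopifnot(is.list(complexes))
  lapply(complexes, function(cx) stopifnot(inherits(cx, "antibody_complex")))
  ids <- vapply(complexes, `[[`, character(1), "complex_id")
  if (anyDuplicated(ids)) {
    stop("duplicate complex ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(complexes = complexes, provenance = as.character(provenance)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d complexes (%d chains)\n",
              length(x$complexes), 2L * length(x$complexes)))
  if (length(x$provenance)) cat(" provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$complexes)

#' Complex identifiers of a dataset, in order
#'
#' @param ds A `labeled_dataset`.
#' @return Character vector of complex ids.
#' @export
complex_ids <- function(ds) vapply(ds$complexes, `[[`, character(1), "complex_id")

#' Read labeled antibody chains from disk
#'
#' Native format is a 4-column TSV with header
#' `complex_id`, `chain_type`, `sequence`, `labels` (labels as a string of
#' `'0'`/`'1'` characters, one per residue). The auxiliary `fasta_pair`
#' format reads a standard FASTA file whose record ids encode
#' `"<complex_id>_H"` / `"<complex_id>_L"`, paired with a 2-column label TSV
#' (`id`, `labels`).
#'
#' Complexes missing either chain are excluded (recorded in the returned
#' provenance and reported via [message()]); residues outside the standard
#' alphabet are normalized to `"X"` with a warning giving the count.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"fasta_pair"`.
#' @param label_path Label TSV, required for `format = "fasta_pair"`.
#' @return A `labeled_dataset`.
#' @export
read_chain_table <- function(path, format = c("tsv", "fasta_pair"), label_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, colClasses = "character", stringsAsFactors = FALSE)
    need <- c("complex_id", "chain_type", "sequence", "labels")
    if (!all(need %in% names(tab))) {
      stop("TSV must have columns: ", paste(need, collapse = ", "))
    }
  } else {
    if (is.null(label_path)) stop("format 'fasta_pair' requires label_path")
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA requires the Biostrings package")
    }
    seqs <- Biostrings::readAAStringSet(path)
    if (length(seqs) == 0L) stop("empty FASTA file: ", path)
    ids <- sub("\\s.*$", "", names(seqs))
    if (!all(grepl("_[HL]$", ids))) {
      stop("FASTA ids must end in _H or _L (e.g. '1abc_H')")
    }
    labs <- utils::read.delim(label_path, colClasses = "character", stringsAsFactors = FALSE)
    if (!all(c("id", "labels") %in% names(labs))) {
      stop("label TSV must have columns: id, labels")
    }
    lab_map <- stats::setNames(labs$labels, labs$id)
    if (!all(ids %in% names(lab_map))) {
      stop("missing labels for: ", paste(setdiff(ids, names(lab_map)), collapse = ", "))
    }
    tab <- data.frame(
      complex_id = sub("_[HL]$", "", ids),
      chain_type = sub("^.*_", "", ids),
      sequence = as.character(seqs),
      labels = unname(lab_map[ids]),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(tab) == 0L) stop("no records in ", path)
  build_dataset_from_records(tab, source = path)
}

build_dataset_from_records <- function(tab, source = "records") {
  chains <- lapply(seq_len(nrow(tab)), function(i) {
    labeled_chain(tab$complex_id[i], tab$chain_type[i], tab$sequence[i], tab$labels[i])
  })
  n_norm <- sum(vapply(chains, function(ch) attr(ch, "n_normalized"), integer(1)))
  if (n_norm > 0) {
    warning(n_norm, " non-standard residue(s) normalized to 'X'", call. = FALSE)
  }
  ids <- vapply(chains, `[[`, character(1), "complex_id")
  types <- vapply(chains, `[[`, character(1), "chain_type")
  if (anyDuplicated(paste(ids, types))) {
    dup <- paste(ids, types)[duplicated(paste(ids, types))]
    stop("duplicate chain records: ", paste(unique(dup), collapse = ", "))
  }
  complexes <- list(); excluded <- character()
  for (id in unique(ids)) {
    idx <- which(ids == id)
    tv <- types[idx]
    if (all(c("H", "L") %in% tv)) {
      complexes[[length(complexes) + 1L]] <- antibody_complex(
        heavy = chains[[idx[tv == "H"]]], light = chains[[idx[tv == "L"]]])
    } else {
      excluded <- c(excluded, id)
    }
  }
  if (length(excluded)) {
    message(length(excluded), " complex(es) missing a chain excluded: ",
            paste(excluded, collapse = ", "))
  }
  prov <- c(paste0("source: ", source),
            if (length(excluded)) paste0("excluded_incomplete: ", length(excluded)),
            if (n_norm > 0) paste0("residues_normalized_to_X: ", n_norm))
  ds <- labeled_dataset(complexes, provenance = prov)
  attr(ds, "excluded") <- excluded
  ds
}

#' Write a labeled dataset to the native 4-column TSV format
#'
#' @param ds A `labeled_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chain_table <- function(ds, path) {
  stopifnot(inherits(ds, "labeled_dataset"))
  rows <- do.call(rbind, lapply(ds$complexes, function(cx) {
    data.frame(
      complex_id = cx$complex_id,
      chain_type = c("H", "L"),
      sequence = c(cx$heavy$sequence, cx$light$sequence),
      labels = c(paste(cx$heavy$labels, collapse = ""),
                 paste(cx$light$labels, collapse = "")),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter complexes by variable-domain length
#'
#' Retains a complex only if both chains fall inside the inclusive
#' `[min_len, max_len]` window (default 110-130 residues, the typical
#' variable-domain range; constant domains and incomplete entries fall
#' outside it).
#'
#' @param ds A `labeled_dataset`.
#' @param min_len,max_len Inclusive length bounds.
#' @return Filtered `labeled_dataset`; the number of removed complexes is
#'   available as `attr(, "n_removed")` and recorded in provenance.
#' @export
filter_by_length <- function(ds, min_len = 110L, max_len = 130L) {
  stopifnot(inherits(ds, "labeled_dataset"), min_len <= max_len)
  keep <- vapply(ds$complexes, function(cx) {
    lh <- chain_length(cx$heavy); ll <- chain_length(cx$light)
    lh >= min_len && lh <= max_len && ll >= min_len && ll <= max_len
  }, logical(1))
  out <- labeled_dataset(ds$complexes[keep],
                         provenance = c(ds$provenance,
                                        sprintf("length_filter: [%d,%d] removed %d",
                                                min_len, max_len, sum(!keep))))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Zero-pad a chain to a fixed length with a padding mask
#'
#' Sequences are right-padded to `padded_length` (default 130). The mask is
#' 1 at real residues and 0 at padding; padded labels are 0 and are excluded
#' from loss and metrics downstream via the mask.
#'
#' @param chain A `labeled_chain` no longer than `padded_length`.
#' @param padded_length Fixed model input length.
#' @return A `padded_chain` object with fields `chain`, `padded_length`,
#'   `mask`, `padded_labels`.
#' @export
pad_and_mask <- function(chain, padded_length = 130L) {
  stopifnot(inherits(chain, "labeled_chain"))
  n <- chain_length(chain)
  if (n > padded_length) {
    stop("chain '", chain$complex_id, "' has ", n, " residues > padded_length ",
         padded_length, "; filter by length first")
  }
  structure(
    list(chain = chain,
         padded_length = as.integer(padded_length),
         mask = c(rep(1L, n), rep(0L, padded_length - n)),
         padded_labels = c(chain$labels, rep(0L, padded_length - n))),
    class = "padded_chain"
  )
}

#' Summarize a labeled dataset
#'
#' Counts complexes, chains, residues and binding residues (over real,
#' unpadded residues only) with a per-chain-type breakdown.
#'
#' @param ds A non-empty `labeled_dataset`.
#' @return A `dataset_summary` list with `n_complexes`, `n_chains`,
#'   `n_residues`, `n_binding`, `binding_fraction` and `per_chain_type`.
#' @export
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (length(ds$complexes) == 0L) stop("cannot summarize an empty dataset")
  chains <- all_chains(ds)
  types <- vapply(chains, `[[`, character(1), "chain_type")
  nres <- vapply(chains, chain_length, integer(1))
  nbind <- vapply(chains, function(ch) sum(ch$labels), integer(1))
  per_type <- do.call(rbind, lapply(c("H", "L"), function(tp) {
    sel <- types == tp
    data.frame(chain_type = tp, n_chains = sum(sel),
               n_residues = sum(nres[sel]), n_binding = sum(nbind[sel]),
               binding_fraction = sum(nbind[sel]) / sum(nres[sel]),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(n_complexes = length(ds$complexes), n_chains = length(chains),
         n_residues = sum(nres), n_binding = sum(nbind),
         binding_fraction = sum(nbind) / sum(nres),
         per_chain_type = per_type),
    class = "dataset_summary"
  )
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("%d complexes, %d chains, %d residues, %d binding (%.2f%%)\n",
              x$n_complexes, x$n_chains, x$n_residues, x$n_binding,
              100 * x$binding_fraction))
  print(x$per_chain_type, row.names = FALSE)
  invisible(x)
}

# flat list of all labeled chains (H then L per complex)
all_chains <- function(ds) {
  unlist(lapply(ds$complexes, function(cx) list(cx$heavy, cx$light)),
         recursive = FALSE)
}

#' Write per-residue predictions to TSV
#'
#' One row per real residue with columns `complex_id`, `chain_type`,
#' `position` (1-based), `residue`, `probability` (6 decimals), `call`.
#'
#' @param records List of records, each a list with `complex_id`,
#'   `chain_type`, `sequence`, `probabilities` (in `[0, 1]`, one per real
#'   residue, padding already stripped) and `calls` (0/1).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    n <- nchar(r$sequence)
    p <- as.numeric(r$probabilities)
    if (length(p) != n) {
      stop("record '", r$complex_id, "': ", length(p),
           " probabilities for ", n, " residues")
    }
    if (any(p < 0 | p > 1)) {
      stop("record '", r$complex_id, "': probabilities outside [0,1]")
    }
    data.frame(complex_id = r$complex_id, chain_type = r$chain_type,
               position = seq_len(n), residue = strsplit(r$sequence, "")[[1]],
               probability = sprintf("%.6f", p),
               call = as.integer(r$calls), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-residue prediction TSV written by [write_predictions()]
#'
#' @param path Prediction TSV path.
#' @return A data.frame with one row per residue.
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(probability = "numeric"))
}
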