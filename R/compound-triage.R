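# Docking-score triage: heavy-atom counts, ligand (binding) efficiency,
# reference-anchored hit calling, and AutoDock Vina result parsing.

#' Count heavy (non-hydrogen) atoms in a SMILES string
#'
#' A minimal SMILES scanner sufficient for heavy-atom counting: it
#' recognises the organic-subset element symbols (\code{B C N O P S F Cl
#' Br I}), their aromatic lowercase forms, and bracket atoms
#' (\code{[...]}), each of which contributes one atom unless its element
#' is hydrogen.  Bond symbols, ring-closure digits (including
#' \code{\%nn}), branches, dots and stereo marks are skipped.  Implicit
#' hydrogens never contribute, which is exactly what a heavy-atom count
#' requires.  No valence model is applied; this is a lexer, not a full
#' cheminformatics parser.
#'
#' @param smiles character vector of SMILES strings.
#' @return integer vector of heavy-atom counts, one per input.
#' @examples
#' heavy_atom_count("CCO")  # ethanol: 3
#' @export
heavy_atom_count <- function(smiles) {
  if (!is.character(smiles) || length(smiles) < 1L)
    abort_validation("'smiles' must be a non-empty character vector")
  vapply(smiles, heavy_atom_count_one, integer(1), USE.NAMES = FALSE)
}

heavy_atom_count_one <- function(smi) {
  if (is.na(smi) || !nzchar(smi))
    abort_parse(sprintf("unparseable SMILES: %s", deparse(smi)))
  chars <- strsplit(smi, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  count <- 0L
  two_letter <- c("Cl", "Br")
  organic   <- c("B", "C", "N", "O", "P", "S", "F", "I")
  aromatic  <- c("b", "c", "n", "o", "p", "s")
  skip_set  <- c(as.character(0:9), "-", "=", "#", "$", ":", "/", "\\",
                 "(", ")", ".", "+", "*")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n)
        abort_parse(sprintf("unparseable SMILES (unclosed bracket): %s", smi))
      body <- substr(smi, i + 1L, j - 1L)
      # bracket grammar: isotope? symbol chiral? hcount? charge? class?
      sym <- sub("^[0-9]*([A-Za-z][a-z]?).*$", "\\1", body)
      if (!grepl("^[0-9]*[A-Za-z]", body) || !nzchar(sym))
        abort_parse(sprintf("unparseable SMILES (bad bracket atom '[%s]'): %s",
                            body, smi))
      # '[H]'/'[2H]' are explicit hydrogens; 'Hg' etc. are heavy.  The
      # symbol regex grabs a following lowercase letter, so plain 'H'
      # here really is hydrogen (an H-count as in '[CH3]' follows the
      # element and is not matched as the symbol).
      if (sym != "H") count <- count + 1L
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", substr(smi, i + 1L, i + 2L)))
        abort_parse(sprintf("unparseable SMILES (bad ring closure): %s", smi))
      i <- i + 3L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% two_letter) {
      count <- count + 1L
      i <- i + 2L
    } else if (ch %in% organic || ch %in% aromatic) {
      count <- count + 1L
      i <- i + 1L
    } else if (ch %in% skip_set) {
      i <- i + 1L
    } else {
      abort_parse(sprintf("unparseable SMILES (unexpected '%s'): %s", ch, smi))
    }
  }
  if (count < 1L)
    abort_parse(sprintf("unparseable SMILES (no atoms): %s", smi))
  count
}

#' Ligand (binding) efficiency per heavy atom
#'
#' Normalises a docking binding energy for molecular size:
#' \deqn{BE = E_b / N_{heavy}}
#' in kcal/mol per heavy atom.  More negative is better; the sign always
#' matches the binding energy.
#'
#' @param binding_energy numeric, docking binding energy in kcal/mol
#'   (typically negative).
#' @param heavy_atoms positive integer(s), non-hydrogen atom count.
#' @return numeric vector of efficiencies, kcal/mol per heavy atom.
#' @examples
#' ligand_efficiency(-11.3, 28)  # cholesterol: -0.4036
#' @export
ligand_efficiency <- function(binding_energy, heavy_atoms) {
  if (!is.numeric(binding_energy) || anyNA(binding_energy))
    abort_validation("'binding_energy' must be numeric without NA")
  if (!is.numeric(heavy_atoms) || anyNA(heavy_atoms) ||
      any(heavy_atoms < 1) || any(heavy_atoms != round(heavy_atoms)))
    abort_domain("'heavy_atoms' must be integers >= 1")
  binding_energy / heavy_atoms
}

# Decimal places of a printed number, e.g. "-0.43" -> 2.
printed_decimals <- function(x) {
  x <- as.character(x)
  ifelse(grepl("\\.", x), nchar(sub("^[^.]*\\.", "", x)), 0L)
}

#' Load a compound score table
#'
#' Reads a CSV/TSV docking-score table with columns \code{compound_id},
#' \code{name}, \code{binding_energy} and either \code{smiles} or
#' \code{heavy_atoms}.  An optional \code{binding_efficiency} column is
#' kept verbatim in \code{be_printed} (so its printed precision is
#' available for verification) as well as numerically.  Heavy-atom
#' counts are derived from SMILES where absent, and a
#' \code{binding_efficiency} column is computed when not supplied.
#'
#' @param path file path; delimiter inferred from extension (.tsv/.tab
#'   means tab) unless \code{sep} is given.
#' @param sep optional field separator override.
#' @return a \code{data.frame} with columns \code{compound_id},
#'   \code{name}, \code{smiles} (possibly NA), \code{heavy_atoms},
#'   \code{binding_energy}, \code{binding_efficiency},
#'   \code{be_printed}, plus any further input columns (e.g.
#'   \code{role}).
#' @export
read_compound_table <- function(path, sep = NULL) {
  if (!file.exists(path))
    abort_validation(sprintf("compound table not found: %s", path))
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  # comment.char must be disabled: '#' is a SMILES triple bond
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          comment.char = "", quote = "\"")
  as_compound_table(df)
}

# Normalise/validate a raw character data.frame into a compound table.
as_compound_table <- function(df) {
  need <- c("compound_id", "name", "binding_energy")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_validation(paste0("compound table lacks column(s): ",
                            paste(miss, collapse = ", ")))
  df$binding_energy <- as.numeric(df$binding_energy)
  if (anyNA(df$binding_energy))
    abort_validation("non-numeric or missing binding_energy values")
  if (!"smiles" %in% names(df)) df$smiles <- NA_character_
  if ("heavy_atoms" %in% names(df)) {
    df$heavy_atoms <- as.integer(df$heavy_atoms)
  } else {
    df$heavy_atoms <- NA_integer_
  }
  needs_count <- is.na(df$heavy_atoms)
  if (any(needs_count)) {
    if (anyNA(df$smiles[needs_count]))
      abort_validation("rows with neither heavy_atoms nor smiles present")
    df$heavy_atoms[needs_count] <- heavy_atom_count(df$smiles[needs_count])
  }
  if ("binding_efficiency" %in% names(df)) {
    df$be_printed <- as.character(df$binding_efficiency)
    df$binding_efficiency <- as.numeric(df$binding_efficiency)
  } else {
    df$be_printed <- NA_character_
    df$binding_efficiency <- ligand_efficiency(df$binding_energy,
                                               df$heavy_atoms)
  }
  df
}

#' The packaged docking worked example
#'
#' Returns the packaged 12-row docking-score table (10 candidate
#' compounds plus the cholesterol and 25-hydroxycholesterol references)
#' with DrugBank accessions, structures, binding energies and printed
#' binding efficiencies.
#'
#' @return a compound table \code{data.frame}; see
#'   \code{\link{read_compound_table}}.
#' @export
npc_docking_table <- function() {
  path <- system.file("extdata", "docking_hits.csv", package = "npcquant",
                      mustWork = TRUE)
  read_compound_table(path)
}

#' Verify printed binding efficiencies against E_b / N_heavy
#'
#' For each row, recomputes the efficiency from the binding energy and
#' heavy-atom count and checks it against the printed value at that
#' row's own printed precision: the row passes iff
#' \eqn{|E_b/N_{heavy} - BE_{printed}| \le 0.5 \times 10^{-d}} where
#' \eqn{d} is the number of printed decimals.
#'
#' @param records compound table with \code{binding_energy},
#'   \code{heavy_atoms} and a printed efficiency (\code{be_printed} or
#'   character \code{binding_efficiency}).
#' @return logical vector, one element per row.
#' @export
verify_efficiency_table <- function(records) {
  records <- ensure_compound_df(records)
  printed <- records$be_printed
  if (is.null(printed) || anyNA(printed)) {
    bad <- if (is.null(printed)) records$compound_id
           else records$compound_id[is.na(printed)]
    abort_validation(paste0("rows without a printed efficiency: ",
                            paste(bad, collapse = ", ")))
  }
  d <- printed_decimals(printed)
  recomputed <- ligand_efficiency(records$binding_energy, records$heavy_atoms)
  abs(recomputed - as.numeric(printed)) <= 0.5 * 10^(-d) + 1e-12
}

ensure_compound_df <- function(records) {
  if (!is.data.frame(records))
    abort_validation("'records' must be a data.frame compound table")
  need <- c("compound_id", "binding_energy", "heavy_atoms")
  miss <- setdiff(need, names(records))
  if (length(miss))
    abort_validation(paste0("compound table lacks column(s): ",
                            paste(miss, collapse = ", ")))
  if (anyNA(records$binding_energy)) {
    bad <- records$compound_id[is.na(records$binding_energy)]
    abort_validation(paste0("rows with missing binding_energy: ",
                            paste(bad, collapse = ", ")))
  }
  if (!"binding_efficiency" %in% names(records) ||
      !is.numeric(records$binding_efficiency))
    records$binding_efficiency <-
      ligand_efficiency(records$binding_energy, records$heavy_atoms)
  records
}

#' Hit criterion anchored to a natural-ligand reference energy
#'
#' Compounds scoring at least as well as the reference (binding energy
#' less than or equal to it, more negative meaning stronger) are hits.
#' The comparison is always inclusive: ties with the reference count as
#' hits.
#'
#' @param reference_energy reference docking energy in kcal/mol; the
#'   default -11.3 is the cholesterol anchor of the packaged worked
#'   example.
#' @return an object of class \code{hit_criterion}.
#' @export
hit_criterion <- function(reference_energy = -11.3) {
  stopifnot_scalar_number(reference_energy, "reference_energy")
  structure(list(reference_energy = reference_energy, inclusive = TRUE),
            class = "hit_criterion")
}

#' @export
print.hit_criterion <- function(x, ...) {
  cat(sprintf("Hit criterion: binding energy <= %.3g kcal/mol (ties are hits)\n",
              x$reference_energy))
  invisible(x)
}

#' Call hits against a reference energy
#'
#' Retains compounds with \code{binding_energy <= reference_energy}
#' (inclusive: boundary ties are hits) and orders them by binding energy
#' ascending, then binding efficiency ascending, then
#' \code{compound_id}.
#'
#' @param records compound table (see \code{\link{read_compound_table}}).
#' @param criterion a \code{\link{hit_criterion}}.
#' @return the hit rows of \code{records}, reordered; possibly zero rows.
#' @export
select_hits <- function(records, criterion = hit_criterion()) {
  if (!inherits(criterion, "hit_criterion"))
    abort_validation("'criterion' must be a hit_criterion object")
  if (is.data.frame(records) && nrow(records) == 0L) return(records)
  records <- ensure_compound_df(records)
  hits <- records[records$binding_energy <= criterion$reference_energy, ,
                  drop = FALSE]
  ord <- order(hits$binding_energy, hits$binding_efficiency,
               hits$compound_id, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Rank a compound table into a triage report
#'
#' Sorts by binding energy ascending (ties: efficiency, then id), adds a
#' \code{rank} column and, if a criterion is supplied, an \code{is_hit}
#' flag.
#'
#' @inheritParams select_hits
#' @param criterion optional \code{\link{hit_criterion}} used to flag hits.
#' @return a \code{data.frame} with columns \code{rank},
#'   \code{compound_id}, \code{name}, \code{binding_energy},
#'   \code{binding_efficiency}[, \code{is_hit}].
#' @export
rank_compounds <- function(records, criterion = NULL) {
  records <- ensure_compound_df(records)
  ord <- order(records$binding_energy, records$binding_efficiency,
               records$compound_id, method = "radix")
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(criterion)) {
    if (!inherits(criterion, "hit_criterion"))
      abort_validation("'criterion' must be a hit_criterion object")
    out$is_hit <- out$binding_energy <= criterion$reference_energy
  }
  keep <- c("rank", "compound_id",
            if ("name" %in% names(out)) "name",
            "binding_energy", "binding_efficiency",
            if (!is.null(criterion)) "is_hit")
  rownames(out) <- NULL
  out[, keep, drop = FALSE]
}

#' Parse AutoDock Vina output into a docking mode list
#'
#' Supports two dialects: \code{"pdbqt"} (result poses carrying
#' \code{REMARK VINA RESULT: <affinity> <rmsd_lb> <rmsd_ub>} lines) and
#' \code{"log"} (the console affinity table with rows
#' \code{mode affinity rmsd_lb rmsd_ub}).  Mode 1 is the best pose and
#' its affinity is reported as \code{best_affinity}; affinities must be
#' non-decreasing, as the engine emits them.
#'
#' @param input path to a file, or a character vector of lines.
#' @param dialect \code{"pdbqt"} or \code{"log"}.
#' @return an object of class \code{docking_modes}: a list with
#'   \code{modes} (data.frame \code{mode}, \code{affinity}) and
#'   \code{best_affinity}.
#' @export
parse_vina_result <- function(input, dialect = c("pdbqt", "log")) {
  dialect <- match.arg(dialect)
  lines <- if (length(input) == 1L && !grepl("\n", input) &&
               file.exists(input)) readLines(input, warn = FALSE)
           else unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  if (dialect == "pdbqt") {
    idx <- grep("^REMARK VINA RESULT:", lines)
    if (!length(idx))
      abort_parse("no 'REMARK VINA RESULT' record found")
    aff <- vapply(idx, function(i) {
      tok <- strsplit(trimws(sub("^REMARK VINA RESULT:", "", lines[i])),
                      "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(tok[1]))
      if (!length(tok) || is.na(v))
        abort_parse(sprintf("non-numeric affinity on line %d", i))
      v
    }, numeric(1))
  } else {
    hdr <- grep("^\\s*mode\\s*\\|", lines)
    start <- if (length(hdr)) {
      sep <- grep("^[-+\\s]+$", lines)
      after <- sep[sep > hdr[1]]
      if (length(after)) after[1] + 1L else hdr[1] + 1L
    } else 1L
    aff <- numeric(0); idx <- integer(0)
    for (i in seq(start, length.out = max(0L, length(lines) - start + 1L))) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(tok) < 2L || !grepl("^[0-9]+$", tok[1])) next
      v <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(v))
        abort_parse(sprintf("non-numeric affinity on line %d", i))
      aff <- c(aff, v); idx <- c(idx, i)
    }
    if (!length(aff))
      abort_parse("no affinity table rows found in log output")
  }
  if (is.unsorted(aff))
    abort_parse("mode affinities are not non-decreasing; corrupt result?")
  structure(list(modes = data.frame(mode = seq_along(aff), affinity = aff),
                 best_affinity = aff[1]),
            class = "docking_modes")
}

#' Serialize a docking mode list back to engine-style text
#'
#' Inverse of \code{\link{parse_vina_result}} up to whitespace: the
#' affinities survive a parse/serialize round trip exactly.
#'
#' @param x a \code{docking_modes} object.
#' @param dialect \code{"pdbqt"} or \code{"log"}.
#' @return character vector of lines.
#' @export
serialize_vina_modes <- function(x, dialect = c("pdbqt", "log")) {
  dialect <- match.arg(dialect)
  if (!inherits(x, "docking_modes"))
    abort_validation("'x' must be a docking_modes object")
  aff <- format(x$modes$affinity, trim = TRUE, digits = 15)
  if (dialect == "pdbqt") {
    sprintf("REMARK VINA RESULT: %10s      0.000      0.000", aff)
  } else {
    c("mode |   affinity | dist from best mode",
      "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
      "-----+------------+----------+----------",
      sprintf("%5d %12s %10.3f %10.3f", x$modes$mode, aff, 0, 0))
  }
}

#' @export
print.docking_modes <- function(x, ...) {
  cat(sprintf("Docking result: %d mode(s), best affinity %.3f kcal/mol\n",
              nrow(x$modes), x$best_affinity))
  invisible(x)
}
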