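AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

DSSP_CODES <- c("H", "G", "I", "T", "B", "S", "E", " ")

#' Parse a classic-format DSSP file
#'
#' Reads the fixed-column residue table emitted by DSSP (<= 3.x, or
#' `dssp --output-format dssp`): one record per residue after the
#' `#  RESIDUE AA STRUCTURE` header. Chain-break records (`!` in the amino
#' acid column) are skipped. Bridge ladder sense follows the DSSP case
#' convention: lowercase ladder letters mark parallel bridges, uppercase
#' antiparallel; a residue carrying both senses is classed antiparallel.
#'
#' @param path path to a DSSP file, or a character vector of its lines.
#' @return A data.frame with one row per residue: `chain`, `resnum`, `aa`,
#'   `ss_code` (one of H, G, I, T, B, S, E or `" "`), `bp1`, `bp2`
#'   (bridge-partner serials, 0 when absent) and `ladder_sense`
#'   (`"parallel"`, `"antiparallel"` or `"none"`).
#' @export
parse_dssp <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  hdr <- grep("#  RESIDUE AA STRUCTURE", lines, fixed = TRUE)
  if (length(hdr) == 0L) stop("DSSP format error: residue header line not found")
  body <- lines[seq(hdr[1L] + 1L, length.out = length(lines) - hdr[1L])]
  body <- body[nzchar(trimws(body))]
  recs <- lapply(seq_along(body), function(i) {
    ln <- body[i]
    aa <- substr(ln, 14L, 14L)
    if (aa == "!") return(NULL)  # chain break
    if (nchar(ln) < 17L) {
      stop(sprintf("DSSP parse error at line %d after header: line too short",
                   i))
    }
    ss <- substr(ln, 17L, 17L)
    if (!ss %in% DSSP_CODES) {
      stop(sprintf("DSSP parse error at line %d: unknown structure code '%s'",
                   i, ss))
    }
    lad <- c(substr(ln, 24L, 24L), substr(ln, 25L, 25L))
    has_par <- any(grepl("[a-z]", lad))
    has_anti <- any(grepl("[A-Z]", lad))
    sense <- if (has_anti) "antiparallel" else if (has_par) "parallel" else "none"
    num <- function(a, b) {
      v <- suppressWarnings(as.integer(substr(ln, a, b)))
      if (is.na(v)) 0L else v
    }
    data.frame(
      chain = substr(ln, 12L, 12L),
      resnum = num(6L, 10L),
      aa = aa,
      ss_code = ss,
      bp1 = num(26L, 29L),
      bp2 = num(30L, 33L),
      ladder_sense = sense,
      stringsAsFactors = FALSE
    )
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) {
    return(data.frame(
      chain = character(), resnum = integer(), aa = character(),
      ss_code = character(), bp1 = integer(), bp2 = integer(),
      ladder_sense = character(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, recs)
}

#' Write a synthetic classic-format DSSP fixture
#'
#' Serializes a residue table in the classic DSSP fixed-column layout so that
#' [parse_dssp()] recovers its semantic content exactly. Intended for building
#' small synthetic test fixtures; it does not run the DSSP algorithm.
#'
#' @param residues data.frame with columns `aa`, `ss_code` and optionally
#'   `chain` (default `"A"`), `resnum` (default sequential), `ladder`
#'   (ladder letter(s), lowercase = parallel, uppercase = antiparallel, `""`
#'   for none), `bp1`, `bp2`. A row with `aa == "!"` emits a chain-break
#'   record.
#' @param path output path; omit to return the lines.
#' @return The file lines, invisibly if `path` is given.
#' @export
write_dssp_fixture <- function(residues, path = NULL) {
  n <- nrow(residues)
  chain <- if ("chain" %in% names(residues)) residues$chain else rep("A", n)
  resnum <- if ("resnum" %in% names(residues)) residues$resnum else seq_len(n)
  ladder <- if ("ladder" %in% names(residues)) residues$ladder else rep("", n)
  bp1 <- if ("bp1" %in% names(residues)) residues$bp1 else rep(0L, n)
  bp2 <- if ("bp2" %in% names(residues)) residues$bp2 else rep(0L, n)
  header <- c(
    "==== Secondary Structure Definition, synthetic fixture ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC"
  )
  body <- vapply(seq_len(n), function(i) {
    if (residues$aa[i] == "!") {
      return(sprintf("%5d        !", i))
    }
    lad <- ladder[i]
    l1 <- substr(paste0(lad, " "), 1L, 1L)
    l2 <- substr(paste0(lad, "  "), 2L, 2L)
    sprintf(
      "%5d%5d %s %s  %s      %s%s%4d%4d%s%4d",
      i, resnum[i], chain[i], residues$aa[i], residues$ss_code[i],
      l1, l2, bp1[i], bp2[i], " ", 0L
    )
  }, character(1))
  lines <- c(header, body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Construct a secondary-structure fraction profile
#'
#' Fractions are percentages of the total residue count. `Others` groups
#' everything that is neither alpha-helix (H) nor beta-sheet (E): turns,
#' bends, 3-10/pi helices, bridges and irregular structure.
#'
#' @param H,E,Others percent alpha-helix, beta-sheet and remainder; must sum
#'   to 100.
#' @param ordered_H,disordered_H split of `H` (helix cores vs. two-residue
#'   helix tips); must sum to `H`.
#' @param E_parallel,E_antiparallel split of `E` by bridge ladder sense; must
#'   sum to `E`.
#' @return An object of class `structure_profile` (a named numeric vector).
#' @export
structure_profile <- function(H, E, Others = 100 - H - E,
                              ordered_H = H, disordered_H = H - ordered_H,
                              E_parallel = 0, E_antiparallel = E - E_parallel) {
  p <- c(H = as.numeric(H)[1L], E = as.numeric(E)[1L],
         Others = as.numeric(Others)[1L],
         ordered_H = as.numeric(ordered_H)[1L],
         disordered_H = as.numeric(disordered_H)[1L],
         E_parallel = as.numeric(E_parallel)[1L],
         E_antiparallel = as.numeric(E_antiparallel)[1L])
  H <- p[["H"]]; E <- p[["E"]]; Others <- p[["Others"]]
  ordered_H <- p[["ordered_H"]]; disordered_H <- p[["disordered_H"]]
  E_parallel <- p[["E_parallel"]]; E_antiparallel <- p[["E_antiparallel"]]
  if (any(p < -1e-9) || any(p > 100 + 1e-9)) {
    stop("structure fractions must lie in [0, 100]")
  }
  if (abs(H + E + Others - 100) > 1e-9) stop("H + E + Others must equal 100")
  if (abs(ordered_H + disordered_H - H) > 1e-9) {
    stop("ordered_H + disordered_H must equal H")
  }
  if (abs(E_parallel + E_antiparallel - E) > 1e-9) {
    stop("E_parallel + E_antiparallel must equal E")
  }
  structure(p, class = "structure_profile")
}

#' @export
print.structure_profile <- function(x, ...) {
  cat("<structure_profile> (% residues)\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Reference structure fractions from parsed DSSP residues
#'
#' H and E are the percentages of residues coded `H` (alpha-helix) and `E`
#' (beta-sheet); `Others = 100 - H - E`. The helix fraction is split into
#' ordered and disordered helix by [ordered_helix_split()] and the sheet
#' fraction by bridge ladder sense via [sheet_sense_split()].
#'
#' @param residues data.frame as returned by [parse_dssp()].
#' @return A [structure_profile].
#' @export
compute_fractions <- function(residues) {
  n <- nrow(residues)
  if (is.null(n) || n == 0L) stop("empty protein: no residues")
  H <- 100 * sum(residues$ss_code == "H") / n
  E <- 100 * sum(residues$ss_code == "E") / n
  hs <- ordered_helix_split(residues)
  es <- sheet_sense_split(residues)
  structure_profile(
    H = H, E = E, Others = 100 - H - E,
    ordered_H = hs[["ordered_H"]], disordered_H = hs[["disordered_H"]],
    E_parallel = es[["E_parallel"]], E_antiparallel = es[["E_antiparallel"]]
  )
}

#' Split the helix fraction into ordered cores and disordered tips
#'
#' For every maximal run of consecutive `H` residues (within one chain) of
#' length L, the inner `max(L - 4, 0)` residues count as ordered helix and the
#' up-to-two residues amputated at each helix end as disordered helix.
#'
#' @param residues data.frame as returned by [parse_dssp()].
#' @return Named numeric: `ordered_H` and `disordered_H`, percent of residues.
#' @export
ordered_helix_split <- function(residues) {
  n <- nrow(residues)
  if (is.null(n) || n == 0L) stop("empty protein: no residues")
  ordered <- 0L
  disord <- 0L
  for (ch in unique(residues$chain)) {
    r <- rle(residues$ss_code[residues$chain == ch] == "H")
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      L <- r$lengths[k]
      o <- max(L - 4L, 0L)
      ordered <- ordered + o
      disord <- disord + (L - o)
    }
  }
  c(ordered_H = 100 * ordered / n, disordered_H = 100 * disord / n)
}

#' Split the sheet fraction by bridge ladder sense
#'
#' Each `E` residue is counted once, by the sense of its bridge ladder(s):
#' parallel (lowercase DSSP ladder letters) or antiparallel (uppercase).
#' Residues bridging both senses, and `E` residues carrying no ladder
#' information (a warning is issued), are counted antiparallel.
#'
#' @param residues data.frame as returned by [parse_dssp()].
#' @return Named numeric: `E_parallel` and `E_antiparallel`, percent of
#'   residues.
#' @export
sheet_sense_split <- function(residues) {
  n <- nrow(residues)
  if (is.null(n) || n == 0L) stop("empty protein: no residues")
  is_e <- residues$ss_code == "E"
  sense <- residues$ladder_sense[is_e]
  if (any(sense == "none")) {
    warning(sum(sense == "none"),
            " E residue(s) without ladder sense counted antiparallel")
  }
  par <- sum(sense == "parallel")
  anti <- sum(sense != "parallel")
  c(E_parallel = 100 * par / n, E_antiparallel = 100 * anti / n)
}

#' Amino-acid composition of a sequence
#'
#' @param sequence character scalar of standard one-letter codes.
#' @return Named numeric over the 20 standard residues, percent of sequence
#'   length; sums to 100. Report rounding (2 decimals) is left to callers.
#' @examples
#' comp <- aa_composition("HSQGTFTSDYSKYLDSRRAQDFVQWLMNT")  # glucagon
#' round(comp[c("Q", "R")], 2)
#' @export
aa_composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "")[[1L]]
  if (length(chars) == 0L) stop("empty sequence")
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("unknown amino-acid letter(s): ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(chars, levels = AA_ALPHABET))
  stats::setNames(100 * as.numeric(counts) / length(chars), AA_ALPHABET)
}

#' Write a TSV report of structure fractions
#'
#' @param profiles named list of [structure_profile] objects (names are
#'   protein ids) or a data.frame with a `protein_id` column.
#' @param path output TSV path.
#' @return `path`, invisibly. Percentages are rounded to 2 decimals on
#'   serialization only.
#' @export
write_fraction_report <- function(profiles, path) {
  if (is.data.frame(profiles)) {
    df <- profiles
  } else {
    df <- do.call(rbind, lapply(profiles, function(p) {
      as.data.frame(as.list(unclass(p)))
    }))
    df <- cbind(protein_id = names(profiles), df)
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 2)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Minimal FASTA reader for the package's own sequence exports (header line
#' per record, sequence possibly wrapped).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records found")
  idx <- cumsum(hdr)
  ids <- sub("^>", "", trimws(lines[hdr]))
  seqs <- vapply(seq_along(ids), function(k) {
    paste0(lines[idx == k & !hdr], collapse = "")
  }, character(1))
  stats::setNames(gsub("\\s", "", seqs), ids)
}
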