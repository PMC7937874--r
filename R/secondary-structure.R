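#' Read a per-residue secondary-structure assignment
#'
#' Accepts either a literal per-residue code string in the DSSP alphabet
#' (`H`, `G`, `I`, `E`, `B`, `T`, `S`, `C` or `-`) or the path to a classic
#' DSSP output file. The assignment is aligned to the residues of one chain of
#' a structure; residues without an assignment (and `-` codes) are stored as
#' coil `C`. DSSP chain-break `!` records are skipped.
#'
#' @param source A code string (e.g. `"HHHHCC"`), `""`/`NULL` for an all-coil
#'   assignment, or a path to a DSSP output file.
#' @param structure Atom tibble the assignment annotates.
#' @param chain_id Chain to annotate.
#' @return Tibble with columns `chain`, `resid`, `ins`, `ss`, one row per
#'   residue of the chain, in chain order.
#' @export
read_secondary_structure <- function(source, structure, chain_id) {
  res <- structure |>
    dplyr::filter(.data$chain == chain_id) |>
    dplyr::distinct(.data$chain, .data$resid, .data$ins)
  if (nrow(res) == 0) abort(paste0("Unknown chain id: ", chain_id))

  if (is.null(source) || identical(source, "")) {
    res$ss <- "C"
    return(res)
  }
  if (length(source) == 1 && file.exists(source) &&
      !grepl("^[HGIEBTSC\\-]+$", source)) {
    ass <- parse_dssp(source)
    ass <- ass[ass$chain == chain_id, , drop = FALSE]
    res <- dplyr::left_join(res, ass, by = c("chain", "resid", "ins"))
    res$ss[is.na(res$ss) | res$ss == "-"] <- "C"
    return(res)
  }
  codes <- strsplit(toupper(source), "")[[1]]
  if (!all(codes %in% c("H", "G", "I", "E", "B", "T", "S", "C", "-"))) {
    abort("Secondary-structure string contains codes outside the DSSP alphabet.")
  }
  if (length(codes) != nrow(res)) {
    abort(paste0(
      "Secondary-structure string length (", length(codes),
      ") does not match residue count of chain ", chain_id,
      " (", nrow(res), ")."
    ))
  }
  res$ss <- ifelse(codes == "-", "C", codes)
  res
}

## Classic DSSP output: the data block follows the '  #  RESIDUE AA' header.
## Fixed columns: PDB residue number 6-10, insertion code 11, chain 12,
## amino acid 14, summary structure code 17. '!' rows are chain breaks.
parse_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)
  if (length(hdr) == 0) abort(paste0("Not a DSSP output file: ", path))
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]
  tibble(
    chain = trimws(substr(body, 12, 12)),
    resid = as.integer(trimws(substr(body, 6, 10))),
    ins = trimws(substr(body, 11, 11)),
    ss = ifelse(trimws(substr(body, 17, 17)) == "", "C",
                substr(body, 17, 17))
  )
}

## Helix-class DSSP codes for the angle force constant; all helical classes
## are treated as helix, as martinize does.
helix_codes <- function() c("H", "G", "I")
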