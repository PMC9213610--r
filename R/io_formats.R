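#' Read a methylation beta matrix from TSV
#'
#' The on-disk format is a tab-separated table with a header row: first
#' column `probe_id`, remaining columns one per sample. Values are beta
#' values (methylated fraction) in \[0, 1\]; empty cells are read as
#' missing (`NA`) and are permitted.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix, probes as rows and samples as columns, with
#'   `rownames` set to probe ids and `colnames` to sample ids.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  if (ncol(tab) < 2L || names(tab)[1L] != "probe_id") {
    stop("malformed beta matrix header: first column must be 'probe_id'")
  }
  probe_ids <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- probe_ids
  validate_beta_matrix(values)
  values
}

#' Write a methylation beta matrix as TSV
#'
#' Canonical serialization: full precision (`%.17g`-equivalent via
#' [format()] with 17 significant digits would be lossy in edge cases, so
#' numbers are written with `format(..., digits = 17)`), `.` decimal,
#' missing values as empty cells. Writing then reading gives back an
#' identical matrix (ids exact, values within 1e-12).
#'
#' @param beta Numeric matrix, probes x samples, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta_matrix(beta)
  num <- matrix(vapply(beta, format_number, character(1L)),
                nrow = nrow(beta), dimnames = dimnames(beta))
  tab <- data.frame(probe_id = rownames(beta), num, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

format_number <- function(x) {
  if (is.na(x)) return(NA_character_)
  formatC(x, digits = 17, format = "g")
}

#' Validate a beta matrix
#'
#' Checks the invariants of the methylation matrix container: unique
#' probe and sample ids, and every non-missing value within \[0, 1\] (a
#' tolerance of 1e-9 absorbs text round-trip error).
#'
#' @param beta Numeric matrix with dimnames.
#' @param tol Bound tolerance for the \[0, 1\] check.
#' @return `beta`, invisibly.
#' @export
validate_beta_matrix <- function(beta, tol = 1e-9) {
  if (!is.matrix(beta) || !is.numeric(beta)) stop("beta must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("beta matrix must carry probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(beta))) stop("duplicate probe ids in beta matrix")
  if (anyDuplicated(colnames(beta))) stop("duplicate sample ids in beta matrix")
  bad <- which(!is.na(beta) & (beta < -tol | beta > 1 + tol), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("beta value out of [0,1]: probe %s, sample %s (value %g)",
                 rownames(beta)[bad[1L, 1L]], colnames(beta)[bad[1L, 2L]],
                 beta[bad[1L, , drop = FALSE]]))
  }
  invisible(beta)
}

#' Read a sample sheet and join species constants
#'
#' The sample sheet is a TSV with columns `sample_id`, `species`,
#' `tissue`, `sex`, `age_years`; the constants file has columns
#' `species`, `max_lifespan_years`, `maturity_years` (both in years).
#' Samples with missing age are dropped with a warning; the number of
#' drops is attached as attribute `"n_dropped"`.
#'
#' @param path Sample sheet TSV.
#' @param species_constants Species constants TSV.
#' @return A data.frame with one row per retained sample and the species
#'   constants joined on.
#' @export
read_sample_sheet <- function(path, species_constants) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("", "NA"))
  need <- c("sample_id", "species", "tissue", "sex", "age_years")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  consts <- read_species_constants(species_constants)
  build_sample_sheet(sheet[need], consts)
}

#' Read a species constants table
#'
#' @param path TSV with columns `species`, `max_lifespan_years`,
#'   `maturity_years`.
#' @return A data.frame of per-species lifespan constants.
#' @export
read_species_constants <- function(path) {
  consts <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "max_lifespan_years", "maturity_years")
  if (!all(need %in% names(consts))) {
    stop("species constants must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(consts$species)) stop("duplicate species in constants table")
  consts[need]
}

# Shared constructor/validator for sample sheets (used by the reader and
# the simulator). Enforces the join and the age/lifespan invariants.
build_sample_sheet <- function(sheet, consts) {
  missing_sp <- setdiff(unique(sheet$species), consts$species)
  if (length(missing_sp) > 0L) {
    stop("species without lifespan constants: ", paste(missing_sp, collapse = ", "))
  }
  if (any(!is.na(sheet$age_years) & sheet$age_years < 0)) {
    stop("negative age_years in sample sheet")
  }
  bad_const <- consts$max_lifespan_years <= 0 | consts$maturity_years <= 0 |
    consts$maturity_years >= consts$max_lifespan_years
  if (any(bad_const)) {
    stop("invalid constants (need 0 < maturity < max lifespan) for: ",
         paste(consts$species[bad_const], collapse = ", "))
  }
  drop <- is.na(sheet$age_years)
  if (any(drop)) {
    warning(sprintf("dropped %d sample(s) with missing age", sum(drop)))
  }
  out <- merge(sheet[!drop, , drop = FALSE], consts, by = "species", sort = FALSE)
  out <- out[match(sheet$sample_id[!drop], out$sample_id),
             c("sample_id", "species", "tissue", "sex", "age_years",
               "max_lifespan_years", "maturity_years")]
  rownames(out) <- NULL
  if (anyDuplicated(out$sample_id)) stop("duplicate sample ids in sample sheet")
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Write a sample sheet and its species constants
#'
#' @param samples Sample sheet data.frame as returned by
#'   [read_sample_sheet()].
#' @param path Sample sheet output TSV.
#' @param constants_path Optional path for the species constants TSV.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path, constants_path = NULL) {
  core <- samples[c("sample_id", "species", "tissue", "sex", "age_years")]
  core$age_years <- vapply(core$age_years, format_number, character(1L))
  utils::write.table(core, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  if (!is.null(constants_path)) {
    consts <- unique(samples[c("species", "max_lifespan_years", "maturity_years")])
    consts$max_lifespan_years <- vapply(consts$max_lifespan_years, format_number, character(1L))
    consts$maturity_years <- vapply(consts$maturity_years, format_number, character(1L))
    utils::write.table(consts, constants_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

TSS_CATEGORIES <- c("promoter", "5'UTR", "exon", "intron", "3'UTR",
                    "downstream", "distal")

#' Read a probe annotation table
#'
#' TSV with columns `probe_id`, `assembly`, `chrom`, `pos` (1-based),
#' `strand`, `mappable_species` (semicolon-separated species labels),
#' `island_flag`, `tss_category`, `chromatin_state`, `prc2_bound`,
#' `gene_symbol`. The assembly string is kept verbatim; `tss_category`
#' must come from the closed vocabulary (promoter, 5'UTR, exon, intron,
#' 3'UTR, downstream, distal).
#'
#' @param path TSV file path.
#' @return A data.frame, one row per probe; `mappable_species` is a list
#'   column of character vectors.
#' @export
read_probe_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  need <- c("probe_id", "assembly", "chrom", "pos", "strand",
            "mappable_species", "island_flag", "tss_category",
            "chromatin_state", "prc2_bound", "gene_symbol")
  if (!all(need %in% names(tab))) {
    stop("probe annotation must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[need]
  tab$mappable_species <- strsplit(as.character(tab$mappable_species), ";",
                                   fixed = TRUE)
  tab$island_flag <- as.logical(tab$island_flag)
  tab$prc2_bound <- as.logical(tab$prc2_bound)
  validate_probe_annotation(tab)
  tab
}

validate_probe_annotation <- function(annotation) {
  if (anyDuplicated(annotation$probe_id)) stop("duplicate probe ids in annotation")
  if (any(is.na(annotation$assembly)) || any(!nzchar(annotation$assembly))) {
    stop("assembly string must be non-empty")
  }
  if (any(annotation$pos < 1L)) stop("probe pos must be >= 1 (1-based)")
  bad <- setdiff(unique(annotation$tss_category), TSS_CATEGORIES)
  if (length(bad) > 0L) {
    stop("unknown tss_category: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(TSS_CATEGORIES, collapse = ", "), ")")
  }
  invisible(annotation)
}

#' Write a probe annotation table
#'
#' @param annotation Annotation data.frame as from [read_probe_annotation()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(annotation, path) {
  validate_probe_annotation(annotation)
  out <- annotation
  out$mappable_species <- vapply(annotation$mappable_species,
                                 paste, character(1L), collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Export probe coordinates as BED6
#'
#' Converts the annotation's 1-based inclusive coordinates to the BED
#' 0-based half-open convention: `start = pos - 1`, `end = pos`. Score is
#' 0; name is the probe id.
#'
#' @param annotation Probe annotation data.frame.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
export_probe_bed <- function(annotation, path) {
  validate_probe_annotation(annotation)
  bed <- data.frame(chrom = annotation$chrom,
                    start = annotation$pos - 1L,
                    end = annotation$pos,
                    name = annotation$probe_id,
                    score = 0L,
                    strand = ifelse(is.na(annotation$strand), ".",
                                    annotation$strand),
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read probe coordinates from a BED6 file
#'
#' Inverse of [export_probe_bed()] for coordinates: returns 1-based
#' positions (`pos = start + 1`).
#'
#' @param path BED file path.
#' @return data.frame with columns `probe_id`, `chrom`, `pos`, `strand`.
#' @export
read_probe_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  data.frame(probe_id = bed$name, chrom = bed$chrom, pos = bed$start + 1L,
             strand = bed$strand, stringsAsFactors = FALSE)
}
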