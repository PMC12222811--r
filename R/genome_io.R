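#' Construct a multi-replicon genome reference
#'
#' A genome reference holds the replicons (chromosomes and plasmids) of a
#' single genome, sorted by descending length with ties broken by id, and
#' designates the longest chromosome as the reference replicon: all copy
#' numbers are reported relative to it (copy number 1).
#'
#' @param ids character vector of unique replicon ids.
#' @param sequences character vector of nucleotide sequences over
#'   `{A,C,G,T,N}` (other IUPAC codes are tolerated and treated like `N`
#'   by the k-mer index).
#' @param roles character vector, each `"chromosome"` or `"plasmid"`.
#'
#' @return An object of class `genome_ref`: a list with `replicons` (a
#'   tibble with columns `id`, `length`, `role`), `sequences` (named
#'   character vector in the same order) and `reference_index` (position
#'   of the longest chromosome; 1 unless a plasmid outranks every
#'   chromosome, a pathology that [apply_genome_filters()] rejects).
#' @seealso [load_genome()], [apply_genome_filters()]
#' @export
genome_ref <- function(ids, sequences, roles) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  roles <- match.arg(roles, c("chromosome", "plasmid"), several.ok = TRUE)
  if (length(ids) != length(sequences) || length(ids) != length(roles))
    stop("ids, sequences and roles must have equal length")
  if (anyDuplicated(ids))
    stop("duplicate replicon id: ", ids[duplicated(ids)][1])
  lens <- nchar(sequences)
  if (any(lens == 0))
    stop("empty sequence for replicon: ", ids[lens == 0][1])
  if (!any(roles == "chromosome"))
    stop("no reference chromosome")
  ord <- order(-lens, ids)
  ids <- ids[ord]; sequences <- sequences[ord]
  roles <- roles[ord]; lens <- lens[ord]
  structure(
    list(
      replicons = tibble::tibble(id = ids, length = lens, role = roles),
      sequences = setNames(sequences, ids),
      reference_index = which(roles == "chromosome")[1]
    ),
    class = "genome_ref"
  )
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("<genome_ref> ", nrow(x$replicons), " replicon(s), reference: ",
      x$replicons$id[x$reference_index], "\n", sep = "")
  print(x$replicons)
  invisible(x)
}

#' Load a multi-replicon reference genome from FASTA
#'
#' Each FASTA record is one replicon. Roles are taken from the optional
#' metadata table when given; otherwise a record whose description line
#' contains the word "plasmid" (case-insensitive) is a plasmid and every
#' other record is a chromosome, mirroring how plasmids are flagged in
#' reference annotation headers.
#'
#' @param fasta_path path to a FASTA file (optionally gzip-compressed).
#' @param metadata optional role table: a data frame with columns
#'   `replicon_id` and `role`, or the path of a tab-separated file with
#'   those columns.
#' @return A [genome_ref()] object.
#' @export
load_genome <- function(fasta_path, metadata = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) stop("no sequences in ", fasta_path)
  desc <- names(seqs)
  ids <- sub("\\s.*$", "", desc)
  if (anyDuplicated(ids))
    stop("duplicate replicon id: ", ids[duplicated(ids)][1])
  if (!is.null(metadata)) {
    if (is.character(metadata))
      metadata <- read.delim(metadata, stringsAsFactors = FALSE)
    if (!all(c("replicon_id", "role") %in% names(metadata)))
      stop("metadata must have columns replicon_id and role")
    roles <- metadata$role[match(ids, metadata$replicon_id)]
    if (anyNA(roles))
      stop("metadata missing role for: ", ids[is.na(roles)][1])
  } else {
    roles <- ifelse(grepl("plasmid", desc, ignore.case = TRUE),
                    "plasmid", "chromosome")
  }
  genome_ref(ids, as.character(seqs), roles)
}

#' Write a genome reference to FASTA
#'
#' The role is appended to each description line so that a round trip
#' through [load_genome()] restores it.
#'
#' @param genome a [genome_ref()] object.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$sequences)
  names(x) <- paste(genome$replicons$id, genome$replicons$role)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Load sequencing reads from FASTQ
#'
#' Reads one single-end file or an R1/R2 pair (optionally
#' gzip-compressed). Mates are counted as independent reads downstream,
#' so no pairing beyond the R1/R2 label is performed. No quality
#' filtering is applied: erroneous reads fail to pseudoalign and drop out
#' of the analysis on their own.
#'
#' @param paths character vector of one (single-end) or two (R1, R2)
#'   FASTQ paths.
#' @return A tibble with columns `id`, `sequence`, `mate`
#'   (`"single"`, `"R1"` or `"R2"`).
#' @export
load_reads <- function(paths) {
  paths <- as.character(paths)
  if (!length(paths) %in% c(1L, 2L))
    stop("paths must contain one FASTQ file or an R1/R2 pair")
  mates <- if (length(paths) == 1L) "single" else c("R1", "R2")
  parts <- lapply(seq_along(paths), function(i) {
    x <- Biostrings::readDNAStringSet(paths[i], format = "fastq")
    tibble::tibble(
      id = sub("\\s.*$", "", names(x)),
      sequence = unname(as.character(x)),
      mate = mates[i]
    )
  })
  if (length(parts) == 2L && nrow(parts[[1]]) != nrow(parts[[2]]))
    stop("mismatched pair counts: ", nrow(parts[[1]]), " vs ",
         nrow(parts[[2]]), " records")
  dplyr::bind_rows(parts)
}

#' Apply the genome-level plasmid filters
#'
#' Two rules: plasmids shorter than `min_plasmid_length` (strictly) are
#' dropped from the genome, and a genome in which any plasmid is longer
#' than its longest chromosome is rejected outright, since the
#' chromosome/plasmid labeling cannot be trusted there.
#'
#' @param genome a [genome_ref()] object.
#' @param min_plasmid_length minimum plasmid length in bp kept
#'   (default 1000; a plasmid of exactly this length is retained).
#' @return A list with `genome` (the filtered [genome_ref()], or `NULL`
#'   when the genome is rejected), `report` (tibble `replicon_id`,
#'   `reason`) and `rejected` (logical).
#' @export
apply_genome_filters <- function(genome, min_plasmid_length = 1000) {
  stopifnot(inherits(genome, "genome_ref"))
  rep <- genome$replicons
  chr_max <- max(rep$length[rep$role == "chromosome"])
  too_long <- rep$role == "plasmid" & rep$length > chr_max
  if (any(too_long)) {
    return(list(
      genome = NULL,
      report = tibble::tibble(
        replicon_id = rep$id[too_long],
        reason = "plasmid_longer_than_chromosome"
      ),
      rejected = TRUE
    ))
  }
  short <- rep$role == "plasmid" & rep$length < min_plasmid_length
  report <- tibble::tibble(
    replicon_id = rep$id[short],
    reason = rep("plasmid_shorter_than_min_length", sum(short))
  )
  if (any(short)) {
    keep <- !short
    genome <- genome_ref(rep$id[keep], genome$sequences[keep],
                         rep$role[keep])
  }
  list(genome = genome, report = report, rejected = FALSE)
}
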