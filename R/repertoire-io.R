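#' Clonotype-table dialects
#'
#' A dialect names the columns of a tab-separated clonotype file and the
#' tokens treated as missing. Two file dialects are supported:
#' \describe{
#'   \item{\code{immunoseq}}{columns \code{amino_acid}, \code{v_gene},
#'     \code{v_family}, \code{reads}, \code{productive_frequency}, plus an
#'     optional \code{nucleotide} column. Rows whose
#'     \code{productive_frequency} is a null token are excluded; a
#'     \code{v_gene} reported as \code{"unresolved"} falls back to the
#'     \code{v_family} value.}
#'   \item{\code{airr}}{columns \code{junction}, \code{junction_aa},
#'     \code{v_call}, \code{duplicate_count}, \code{productive}.}
#' }
#'
#' @param name One of \code{"immunoseq"}, \code{"airr"}.
#' @param null_tokens Strings treated as missing (case-insensitive).
#' @return An object of class \code{clonotype_dialect}.
#' @export
clonotype_dialect <- function(name = c("immunoseq", "airr"),
                              null_tokens = c("null", "NA", "")) {
  name <- match.arg(name)
  column_map <- switch(name,
    immunoseq = c(cdr3_nt = "nucleotide", cdr3_aa = "amino_acid",
                  v_gene = "v_gene", v_family = "v_family",
                  read_count = "reads",
                  productive_frequency = "productive_frequency"),
    airr = c(cdr3_nt = "junction", cdr3_aa = "junction_aa",
             v_call = "v_call", read_count = "duplicate_count",
             productive = "productive"))
  structure(list(name = name, column_map = column_map,
                 null_tokens = tolower(null_tokens)),
            class = "clonotype_dialect")
}

.as_dialect <- function(dialect) {
  if (inherits(dialect, "clonotype_dialect")) return(dialect)
  clonotype_dialect(dialect)
}

#' Construct a TCRB repertoire
#'
#' A repertoire is a sample's set of clones — unique TCRB nucleotide
#' rearrangements with an allele-stripped V-gene call — plus metadata. Clone
#' frequencies are always recomputed from read counts, and clones sharing the
#' identity key \code{(cdr3_nt, v_gene)} are merged by summing reads.
#'
#' @param clones data.frame with columns \code{cdr3_nt} (may be \code{NA}),
#'   \code{cdr3_aa}, \code{v_call}, \code{read_count}, and optionally
#'   \code{productive} (default \code{TRUE}).
#' @param sample_id Sample identifier string.
#' @param dialect Provenance: \code{"immunoseq"}, \code{"airr"} or
#'   \code{"synthetic"}.
#' @param validate Check internal invariants (frequency normalisation, key
#'   uniqueness, translation consistency of in-frame junctions).
#' @return An object of class \code{tcr_repertoire}: a list with elements
#'   \code{sample_id}, \code{clones} (data.frame with recomputed
#'   \code{frequency} and \code{v_gene}), \code{total_reads}, \code{dialect}.
#' @export
tcr_repertoire <- function(clones, sample_id = "sample",
                           dialect = "synthetic", validate = TRUE) {
  required <- c("cdr3_aa", "v_call", "read_count")
  missing_cols <- setdiff(required, names(clones))
  if (length(missing_cols)) {
    stop("clone table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(clones)) stop("empty repertoire: no clones retained")
  if (is.null(clones$cdr3_nt)) clones$cdr3_nt <- NA_character_
  if (is.null(clones$productive)) clones$productive <- TRUE
  clones$cdr3_nt <- toupper(as.character(clones$cdr3_nt))
  clones$cdr3_aa <- toupper(as.character(clones$cdr3_aa))
  clones$v_call <- as.character(clones$v_call)
  clones$v_gene <- strip_allele(clones$v_call)
  clones$read_count <- as.numeric(clones$read_count)
  if (any(is.na(clones$read_count)) || any(clones$read_count < 0)) {
    stop("read counts must be non-negative numbers")
  }
  clones <- .merge_clone_rows(clones)
  total <- sum(clones$read_count)
  if (total <= 0) stop("empty repertoire: zero total reads")
  clones$frequency <- clones$read_count / total
  rownames(clones) <- NULL
  obj <- structure(list(sample_id = as.character(sample_id),
                        clones = clones[, c("cdr3_nt", "cdr3_aa", "v_call",
                                            "v_gene", "read_count",
                                            "frequency", "productive")],
                        total_reads = total,
                        dialect = dialect),
                   class = "tcr_repertoire")
  if (validate) .validate_repertoire(obj)
  obj
}

# merge rows sharing the clone identity key (cdr3_nt, v_gene); rows with no
# nucleotide sequence never merge (each is taken as a distinct rearrangement)
.merge_clone_rows <- function(clones) {
  nt <- clones$cdr3_nt
  surrogate <- ifelse(is.na(nt) | !nzchar(nt),
                      paste0("\r.row", seq_len(nrow(clones))), nt)
  key <- paste(surrogate, clones$v_gene, sep = "\r")
  if (!anyDuplicated(key)) return(clones)
  first <- !duplicated(key)
  merged <- clones[first, , drop = FALSE]
  merged$read_count <- as.numeric(
    tapply(clones$read_count, factor(key, levels = key[first]), sum))
  merged
}

.validate_repertoire <- function(x) {
  cl <- x$clones
  stopifnot(abs(sum(cl$frequency) - 1) < 1e-9)
  if (any(grepl("*", cl$v_gene, fixed = TRUE))) {
    stop("v_gene still carries an allele designator")
  }
  if (abs(x$total_reads - sum(cl$read_count)) > 1e-9) {
    stop("total_reads does not match the clone read-count sum")
  }
  has_nt <- !is.na(cl$cdr3_nt) & nzchar(cl$cdr3_nt)
  key <- paste(cl$cdr3_nt[has_nt], cl$v_gene[has_nt], sep = "\r")
  if (anyDuplicated(key)) stop("duplicate clone identity key (cdr3_nt, v_gene)")
  # translation check only where the nucleotide column is the junction itself
  chk <- has_nt & cl$productive & nchar(cl$cdr3_nt) == 3L * nchar(cl$cdr3_aa)
  if (any(chk)) {
    aa <- translate_cdr3(cl$cdr3_nt[chk])
    if (!all(aa == cl$cdr3_aa[chk])) {
      stop("productive clone whose junction translation differs from cdr3_aa")
    }
  }
  invisible(x)
}

#' Read a clonotype table
#'
#' Reads a tab-separated clonotype file in either supported dialect and
#' applies the dialect's normalisation rules: for the ImmunoSeq dialect, rows
#' with a null \code{productive_frequency} are excluded and an
#' \code{"unresolved"} \code{v_gene} is assigned the \code{v_family} value.
#' V-gene calls are allele-stripped, duplicate \code{(cdr3_nt, v_gene)} rows
#' are merged by summing reads, and frequencies are recomputed as
#' \code{read_count / total retained reads} (the file's own frequency column
#' is used only as an exclusion flag).
#'
#' @param path Path to a tab-separated clonotype file with a header row.
#' @param dialect \code{"immunoseq"}, \code{"airr"}, or a
#'   \code{\link{clonotype_dialect}} object.
#' @param sample_id Sample identifier; defaults to the file name sans
#'   extension.
#' @param drop_out_of_frame Additionally exclude rearrangements whose
#'   junction is out of frame or contains a stop codon. Default off.
#' @return A \code{\link{tcr_repertoire}}.
#' @examples
#' path <- system.file("extdata", "example_immunoseq.tsv",
#'                     package = "tcrconv")
#' rep <- read_clonotype_table(path, dialect = "immunoseq")
#' repertoire_summary(rep)
#' @export
read_clonotype_table <- function(path, dialect = "immunoseq",
                                 sample_id = NULL,
                                 drop_out_of_frame = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  dialect <- .as_dialect(dialect)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  cm <- dialect$column_map
  optional <- if (dialect$name == "immunoseq") "cdr3_nt" else character()
  needed <- cm[setdiff(names(cm), optional)]
  absent <- setdiff(needed, names(tab))
  if (length(absent)) {
    stop("clonotype file lacks mandatory column(s): ",
         paste(absent, collapse = ", "))
  }
  if (dialect$name == "immunoseq") {
    keep <- !(tolower(tab[[cm[["productive_frequency"]]]]) %in%
                dialect$null_tokens)
    tab <- tab[keep, , drop = FALSE]
    if (!nrow(tab)) stop("empty repertoire: no rows retained from ", path)
    v <- tab[[cm[["v_gene"]]]]
    unresolved <- tolower(v) == "unresolved"
    v[unresolved] <- tab[[cm[["v_family"]]]][unresolved]
    clones <- data.frame(
      cdr3_nt = if (cm[["cdr3_nt"]] %in% names(tab))
        tab[[cm[["cdr3_nt"]]]] else NA_character_,
      cdr3_aa = tab[[cm[["cdr3_aa"]]]],
      v_call = v,
      read_count = as.numeric(tab[[cm[["read_count"]]]]),
      productive = TRUE,
      stringsAsFactors = FALSE)
  } else {
    prod <- toupper(tab[[cm[["productive"]]]]) %in% c("T", "TRUE", "1", "YES")
    clones <- data.frame(
      cdr3_nt = tab[[cm[["cdr3_nt"]]]],
      cdr3_aa = tab[[cm[["cdr3_aa"]]]],
      v_call = tab[[cm[["v_call"]]]],
      read_count = as.numeric(tab[[cm[["read_count"]]]]),
      productive = prod,
      stringsAsFactors = FALSE)
  }
  if (drop_out_of_frame) {
    nt <- toupper(clones$cdr3_nt)
    in_frame <- is.na(nt) | !nzchar(nt) |
      (nchar(nt) %% 3L == 0L & !grepl("[^ACGT]", nt))
    ok <- in_frame
    tr <- ok & !is.na(nt) & nzchar(nt)
    ok[tr] <- !has_stop(translate_cdr3(nt[tr]))
    clones <- clones[ok, , drop = FALSE]
  }
  if (!nrow(clones)) stop("empty repertoire: no rows retained from ", path)
  tcr_repertoire(clones, sample_id = sample_id,
                 dialect = paste0(dialect$name, "_like"))
}

#' Write a clonotype table
#'
#' Writes a repertoire as a tab-separated clonotype file in the requested
#' dialect. Reading the file back with \code{\link{read_clonotype_table}}
#' reproduces the clone set, read counts, and frequencies.
#'
#' @param repertoire A \code{\link{tcr_repertoire}}.
#' @param path Output file path.
#' @param dialect \code{"immunoseq"} or \code{"airr"}.
#' @return Invisibly, \code{path}.
#' @export
write_clonotype_table <- function(repertoire, path, dialect = "immunoseq") {
  stopifnot(inherits(repertoire, "tcr_repertoire"))
  dialect <- .as_dialect(dialect)
  cl <- repertoire$clones
  if (!nrow(cl)) stop("empty repertoire")
  if (dialect$name == "immunoseq") {
    out <- data.frame(
      nucleotide = cl$cdr3_nt,
      amino_acid = cl$cdr3_aa,
      v_gene = cl$v_gene,
      v_family = sub("-.*$", "", cl$v_gene),
      reads = cl$read_count,
      productive_frequency = signif(cl$frequency, 10),
      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      junction = cl$cdr3_nt,
      junction_aa = cl$cdr3_aa,
      v_call = cl$v_call,
      duplicate_count = cl$read_count,
      productive = ifelse(cl$productive, "T", "F"),
      stringsAsFactors = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat("TCRB repertoire '", x$sample_id, "' (", x$dialect, ")\n", sep = "")
  cat("  clones:      ", nrow(x$clones), "\n", sep = "")
  cat("  total reads: ", format(x$total_reads, big.mark = ","), "\n", sep = "")
  top <- x$clones[order(-x$clones$frequency)[seq_len(min(3, nrow(x$clones)))], ]
  cat("  top clone frequency: ", signif(top$frequency[1], 3), "\n", sep = "")
  invisible(x)
}
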