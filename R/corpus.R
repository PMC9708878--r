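#' Study corpora of case-control genotype counts
#'
#' A *study corpus* is the input container of the package: one row per
#' case-control study arm-pair, holding the three genotype counts of each arm
#' (common homozygote, heterozygote, variant homozygote), a disease etiology
#' label, the allele labels, and optional free-form metadata columns. It is an
#' ordinary `data.frame` with class `"study_corpus"`, so all base subsetting
#' and inspection tools apply.
#'
#' Required columns: `study_id`, `polymorphism`, `disease`, `case_aa`,
#' `case_ab`, `case_bb`, `ctrl_aa`, `ctrl_ab`, `ctrl_bb`, `allele_common`,
#' `allele_variant`. Counts must be non-negative integers and `study_id`
#' values unique; row order is preserved everywhere downstream.
#'
#' @param x A `data.frame` with the columns above.
#' @param provenance Free-text note on where the table came from.
#'
#' @return A `study_corpus` object (a validated `data.frame`).
#' @seealso [read_study_table()], [load_fixture()], [aggregate_counts()]
#' @export
#' @examples
#' corp <- load_fixture("tgfb1_509")
#' nrow(corp)
#' aggregate_counts(corp)
as_study_corpus <- function(x, provenance = "unspecified") {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.corpus_required_cols, names(x))
  if (length(missing_cols) > 0L) {
    stop("study table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in .corpus_count_cols) {
    v <- x[[col]]
    if (is.character(v)) {
      v_num <- suppressWarnings(as.numeric(v))
    } else {
      v_num <- as.numeric(v)
    }
    bad <- which(is.na(v_num) | v_num < 0 | v_num != floor(v_num))
    if (length(bad) > 0L) {
      stop(sprintf("column '%s': non-negative integer count required, offending row(s): %s",
                   col, paste(bad, collapse = ", ")), call. = FALSE)
    }
    x[[col]] <- as.integer(v_num)
  }
  x$study_id <- as.character(x$study_id)
  dup <- unique(x$study_id[duplicated(x$study_id)])
  if (length(dup) > 0L) {
    stop("duplicate study_id value(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(x$polymorphism))) {
    stop("polymorphism labels must be non-empty", call. = FALSE)
  }
  # reported arm sizes, when present, are checked against genotype sums;
  # genotype sums win and a mismatch is only warned about
  for (arm in c("case", "ctrl")) {
    rep_col <- if (arm == "case") "n_case" else "n_control"
    if (rep_col %in% names(x)) {
      gsum <- x[[paste0(arm, "_aa")]] + x[[paste0(arm, "_ab")]] +
        x[[paste0(arm, "_bb")]]
      rep_n <- suppressWarnings(as.integer(x[[rep_col]]))
      x[[rep_col]] <- rep_n
      bad <- which(!is.na(rep_n) & rep_n != gsum)
      if (length(bad) > 0L) {
        warning(sprintf("reported %s differs from genotype sum for: %s (genotype sums used)",
                        rep_col, paste(x$study_id[bad], collapse = "; ")),
                call. = FALSE)
      }
    }
  }
  rownames(x) <- NULL
  attr(x, "provenance") <- provenance
  class(x) <- c("study_corpus", "data.frame")
  x
}

.corpus_required_cols <- c(
  "study_id", "polymorphism", "disease",
  "case_aa", "case_ab", "case_bb", "ctrl_aa", "ctrl_ab", "ctrl_bb",
  "allele_common", "allele_variant"
)

.corpus_count_cols <- c("case_aa", "case_ab", "case_bb",
                        "ctrl_aa", "ctrl_ab", "ctrl_bb")

#' Read a study table from disk
#'
#' Reads a delimited genotype-count study table (UTF-8, header required) and
#' validates it into a [study corpus][as_study_corpus].
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A `study_corpus`.
#' @export
read_study_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "tsv") "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                         colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8", stringsAsFactors = FALSE,
                         comment.char = "")
  as_study_corpus(x, provenance = path)
}

#' Write a study corpus back to disk
#'
#' Deterministic inverse of [read_study_table()]: a written corpus reads back
#' with identical counts and metadata.
#'
#' @param corpus A `study_corpus`.
#' @inheritParams read_study_table
#' @return Invisibly, `path`.
#' @export
write_study_table <- function(corpus, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  utils::write.table(as.data.frame(corpus), path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Bundled study corpora
#'
#' Returns one of the three packaged corpora of published case-control studies
#' of TGF-beta-1 polymorphisms in chronic liver disease: the promoter variant
#' -509C/T (rs1800469, 25 study arms), codon 10 Leu/Pro (rs1800470, 18 study
#' arms) and codon 25 Arg/Pro (rs1800471, 20 study arms). Each table carries
#' genotype counts for both arms, the disease etiology, and the published
#' Hardy-Weinberg p-values (`hwe_case` / `hwe_control`; `/` marks a
#' monomorphic arm) as reference metadata.
#'
#' @param polymorphism One of `"tgfb1_509"`, `"tgfb1_codon10"`,
#'   `"tgfb1_codon25"`.
#' @return A `study_corpus`.
#' @export
#' @examples
#' nrow(load_fixture("tgfb1_codon10"))  # 18
load_fixture <- function(polymorphism) {
  valid <- c("tgfb1_509", "tgfb1_codon10", "tgfb1_codon25")
  if (!is.character(polymorphism) || length(polymorphism) != 1L ||
      !(polymorphism %in% valid)) {
    stop("unknown fixture; valid names: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  path <- system.file("extdata", paste0(polymorphism, ".tsv"),
                      package = "snpmeta", mustWork = TRUE)
  read_study_table(path, dialect = "tsv")
}

#' Study and sample totals of a corpus
#'
#' @param corpus A `study_corpus`.
#' @return A list with `k` (number of studies), `n_case_total` and
#'   `n_control_total` (summed arm sizes from genotype counts).
#' @export
aggregate_counts <- function(corpus) {
  stopifnot(inherits(corpus, "study_corpus") || is.data.frame(corpus))
  list(
    k = nrow(corpus),
    n_case_total = sum(corpus$case_aa + corpus$case_ab + corpus$case_bb),
    n_control_total = sum(corpus$ctrl_aa + corpus$ctrl_ab + corpus$ctrl_bb)
  )
}

#' @export
print.study_corpus <- function(x, ...) {
  tot <- aggregate_counts(x)
  cat(sprintf("Study corpus: %d studies (%s), %d cases / %d controls\n",
              tot$k, paste(unique(x$polymorphism), collapse = ", "),
              tot$n_case_total, tot$n_control_total))
  cat("Provenance:", attr(x, "provenance") %||% "unspecified", "\n\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a result object
#'
#' Deterministic writer for package result objects. Data frames go to TSV
#' with fixed column order; any other object (pooled fits, reports, lists)
#' goes to JSON with fixed key order and numbers rendered at 6 significant
#' digits. Two writes of the same object are byte-identical.
#'
#' @param results The object to serialize.
#' @param path Output path (parent directory must exist).
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir,
                             call. = FALSE)
  if (format == "tsv") {
    df <- as.data.frame(results)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, 6))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    x <- .to_plain(results)
    json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(6),
                             null = "null", na = "null", pretty = TRUE)
    writeLines(json, path, useBytes = TRUE)
  }
  invisible(path)
}

# strip classes/attributes so jsonlite renders stable plain structures
.to_plain <- function(x) {
  if (inherits(x, "meta_or")) {
    return(list(
      schema_version = "1.0",
      polymorphism = x$polymorphism, contrast = x$contrast,
      model = x$model, k = x$k, n_case = x$n_case, n_control = x$n_control,
      or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
      z = x$z, p = x$p,
      q = x$het$q, p_het = x$het$p_het, i2 = x$het$i2, tau2 = x$het$tau2,
      dropped = x$dropped
    ))
  }
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, .to_plain))
  x
}
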