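#' Write a connectome dataset as per-subject CSV matrices plus a manifest
#'
#' Each subject's adjacency matrix goes to `<subject_id>.csv` (comma-separated,
#' no header, scientific notation with 17 significant digits, so the
#' read/write round trip is lossless at full double precision), and a
#' `manifest.tsv` lists `subject_id`, `cohort`, `sex` (`female`/`male`) and
#' the matrix file name.
#'
#' @param dataset A `connectome_dataset` or list of `connectome_graph`s.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @seealso [load_manifest()]
#' @export
write_connectomes <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vapply(dataset, function(g) {
    file <- paste0(g$subject_id, ".csv")
    lines <- apply(g$adjacency, 1, function(r)
      paste(sprintf("%.17g", r), collapse = ","))
    writeLines(lines, file.path(dir, file))
    paste(g$subject_id, g$cohort,
          if (g$label == 1) "female" else "male", file, sep = "\t")
  }, character(1))
  manifest <- file.path(dir, "manifest.tsv")
  writeLines(c("subject_id\tcohort\tsex\tfile", rows), manifest)
  invisible(manifest)
}

#' Load a connectome dataset from a manifest
#'
#' Reads the manifest TSV and every referenced matrix file, validating that
#' each matrix is square, exactly symmetric, non-negative and finite with a
#' zero diagonal, and that all subjects share the same region count. The
#' first violation aborts with a diagnostic naming the subject (and, for
#' asymmetry, the offending entry).
#'
#' @param path Path to a manifest TSV with columns `subject_id`, `cohort`,
#'   `sex`, `file` (matrix paths relative to the manifest).
#' @return A `connectome_dataset`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "cohort", "sex", "file")
  if (!all(required %in% names(man))) {
    stop("manifest must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  bad_cohort <- setdiff(unique(man$cohort), c("adult", "pediatric"))
  if (length(bad_cohort)) {
    stop("unknown cohort token(s): ", paste(bad_cohort, collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- setdiff(unique(man$sex), c("female", "male"))
  if (length(bad_sex)) {
    stop("unknown sex token(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(path)
  n_regions <- NULL
  graphs <- lapply(seq_len(nrow(man)), function(i) {
    f <- file.path(base, man$file[i])
    if (!file.exists(f)) {
      stop("matrix file for subject ", man$subject_id[i], " not found: ", f,
           call. = FALSE)
    }
    A <- as.matrix(utils::read.csv(f, header = FALSE,
                                   colClasses = "numeric"))
    dimnames(A) <- NULL
    tryCatch(
      check_square_symmetric_nonneg(A, tol = 0, context = "adjacency"),
      error = function(e) {
        stop("subject ", man$subject_id[i], ": ", conditionMessage(e),
             call. = FALSE)
      })
    if (any(diag(A) != 0)) {
      stop("subject ", man$subject_id[i], ": adjacency diagonal must be zero",
           call. = FALSE)
    }
    if (is.null(n_regions)) {
      n_regions <<- nrow(A)
    } else if (nrow(A) != n_regions) {
      stop("subject ", man$subject_id[i], " has ", nrow(A),
           " regions; expected ", n_regions, call. = FALSE)
    }
    connectome_graph(A, label = as.integer(man$sex[i] == "female"),
                     cohort = man$cohort[i], subject_id = man$subject_id[i])
  })
  structure(graphs, class = "connectome_dataset")
}
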