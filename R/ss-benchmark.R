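#' Secondary-structure label alphabet
#'
#' Eight states plus `X`: `B` isolated beta-bridge, `E` extended strand,
#' `G` 3-10 helix, `H` alpha-helix, `I` pi-helix, `T` turn, `S` bend
#' (DSSP only), `C` loop/irregular, `X` no assignment.
#'
#' @return Character vector of the nine codes.
#' @export
ss_alphabet <- function() c("B", "E", "G", "H", "I", "T", "S", "C", "X")

# Fixed three-state grouping used by the Q3 score.
ss3_groups <- function() {
  list(strand = c("B", "E"), helix = c("G", "H", "I"), coil = c("C", "S", "T"))
}

#' Three-state class of each eight-state label
#'
#' @param codes character vector of labels from [ss_alphabet()].
#' @return Character vector: `"strand"`, `"helix"`, `"coil"` or `NA` for
#'   `X`.
#' @export
ss3_class <- function(codes) {
  g <- ss3_groups()
  out <- rep(NA_character_, length(codes))
  for (cl in names(g)) out[codes %in% g[[cl]]] <- cl
  out
}

#' Joint probability of cluster assignment and secondary-structure label
#'
#' For every sample the soft cluster probability (posterior responsibility
#' under the mixture, background zeta = 0) is accumulated into the row of
#' its label: `P(A, y) = (1/N) * sum over samples with label y of p_A(x)`.
#' The table sums to one over all clusters and labels.
#'
#' @param x features the model was fitted on (data frame or matrix).
#' @param labels per-sample labels from [ss_alphabet()].
#' @param model a `pamm` model.
#' @param hard use hard (argmax) assignments instead of soft
#'   responsibilities.
#' @return An `ss_joint` object: the K x L probability matrix with
#'   dimnames, plus `n_residues`.
#' @export
joint_ss_table <- function(x, labels, model, hard = FALSE) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), ss_alphabet())
  if (length(bad) > 0L) {
    stop("labels outside the alphabet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  X <- as_feature_matrix(x)
  if (nrow(X) != length(labels)) stop("one label per feature row required", call. = FALSE)
  R <- pamm_pmi(model, X, zeta = 0)
  if (hard) {
    hardR <- matrix(0, nrow(R), ncol(R))
    hardR[cbind(seq_len(nrow(R)), max.col(R, ties.method = "first"))] <- 1
    R <- hardR
  }
  lab_lv <- intersect(ss_alphabet(), unique(labels))
  P <- vapply(lab_lv, function(lv) colSums(R[labels == lv, , drop = FALSE]),
              numeric(ncol(R)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L, dimnames = list(NULL, lab_lv))
  P <- P / length(labels)
  rownames(P) <- seq_len(nrow(P))
  structure(list(table = P, n_residues = length(labels)), class = "ss_joint")
}

#' @export
print.ss_joint <- function(x, ...) {
  cat("<ss_joint> P(cluster, label), N =", x$n_residues, "\n")
  print(round(x$table, 4))
  invisible(x)
}

#' Tidy a joint cluster-label table
#'
#' @param x an `ss_joint` object.
#' @param ... unused.
#' @return Long tibble with `cluster`, `label`, `p_joint`,
#'   `p_label_given_cluster`, `p_cluster_given_label`.
#' @export
tidy.ss_joint <- function(x, ...) {
  P <- x$table
  long <- tidyr::expand_grid(cluster = seq_len(nrow(P)),
                             label = colnames(P))
  long$p_joint <- P[cbind(long$cluster, match(long$label, colnames(P)))]
  pa <- rowSums(P); py <- colSums(P)
  long$p_label_given_cluster <- long$p_joint / pa[long$cluster]
  long$p_cluster_given_label <- long$p_joint / py[match(long$label, colnames(P))]
  long
}

# Drop the X column (unassigned residues) and renormalize.
drop_x <- function(table) {
  P <- table$table
  P <- P[, colnames(P) != "X", drop = FALSE]
  s <- sum(P)
  if (s == 0) stop("table is empty after removing unassigned residues", call. = FALSE)
  P / s
}

#' Map clusters to strand/helix/coil
#'
#' Each cluster goes to the three-state group of the label maximizing
#' `P(y | A)` (with `X` excluded from the argmax). Exact ties fall back to
#' coil, the conservative default, and are reported.
#'
#' @param table an `ss_joint` from [joint_ss_table()].
#' @return Tibble with `cluster`, `best_label`, `class`.
#' @export
map_ss_clusters <- function(table) {
  P <- drop_x(table)
  best <- character(nrow(P)); cls <- character(nrow(P))
  for (k in seq_len(nrow(P))) {
    row <- P[k, ]
    hits <- which(row == max(row))
    if (length(hits) > 1L) {
      message("cluster ", k, ": tie over labels ",
              paste(colnames(P)[hits], collapse = "/"), "; assigning coil")
      best[k] <- colnames(P)[hits[1]]
      cls[k] <- "coil"
    } else {
      best[k] <- colnames(P)[hits]
      cls[k] <- ss3_class(best[k])
    }
  }
  tibble::tibble(cluster = seq_len(nrow(P)), best_label = best, class = cls)
}

#' Q3 score of a cluster-label table
#'
#' Sum of the joint probabilities falling in the matched three-state
#' groups: `Q3 = Q_strand + Q_helix + Q_coil`, where each term sums
#' `P(cluster, label)` over the clusters mapped to that class and the
#' labels belonging to it. Unassigned (`X`) residues are removed before
#' normalization.
#'
#' @param table an `ss_joint`.
#' @param mapping cluster mapping from [map_ss_clusters()]; recomputed if
#'   `NULL`.
#' @return Q3 in `[0, 1]`.
#' @export
q3_score <- function(table, mapping = NULL) {
  mapping <- mapping %||% map_ss_clusters(table)
  P <- drop_x(table)
  g <- ss3_groups()
  total <- 0
  for (cl in names(g)) {
    rows <- mapping$cluster[mapping$class == cl]
    cols <- intersect(g[[cl]], colnames(P))
    if (length(rows) > 0L && length(cols) > 0L) {
      total <- total + sum(P[rows, cols, drop = FALSE])
    }
  }
  total
}

#' Q8 score of a cluster-label table
#'
#' Each cluster predicts a single eight-state label (its argmax
#' `P(y | A)` unless an explicit assignment is given); the score is the
#' total joint probability the predictions capture.
#'
#' @param table an `ss_joint`.
#' @param assignment optional character vector, one label per cluster.
#' @return Q8 in `[0, 1]`.
#' @export
q8_score <- function(table, assignment = NULL) {
  P <- drop_x(table)
  if (is.null(assignment)) {
    assignment <- colnames(P)[max.col(P, ties.method = "first")]
  }
  stopifnot(length(assignment) == nrow(P))
  sum(P[cbind(seq_len(nrow(P)), match(assignment, colnames(P)))], na.rm = TRUE)
}

#' Read per-residue secondary-structure labels
#'
#' Supports classic DSSP output, STRIDE output (`ASG` records) and a plain
#' TSV with header columns `chain`, `resno`, `code` (an optional
#' `structure_id` column is carried through). Blank assignment columns map
#' to `X`; codes outside the alphabet are an error.
#'
#' @param path label file.
#' @param dialect `"tsv"`, `"dssp"` or `"stride"`.
#' @return Tibble with `chain`, `resno`, `code`.
#' @export
read_ss_labels <- function(path, dialect = c("tsv", "dssp", "stride")) {
  dialect <- match.arg(dialect)
  out <- switch(dialect,
    tsv = {
      df <- utils::read.delim(path, stringsAsFactors = FALSE)
      if (!all(c("chain", "resno", "code") %in% names(df))) {
        stop("TSV label file needs columns chain, resno, code", call. = FALSE)
      }
      tibble::tibble(chain = as.character(df$chain),
                     resno = as.integer(df$resno),
                     code = trimws(df$code))
    },
    dssp = {
      lines <- readLines(path, warn = FALSE)
      start <- grep("^  #  RESIDUE", lines)
      if (length(start) == 0L) stop("not DSSP output: header line missing", call. = FALSE)
      body <- lines[(start[1] + 1L):length(lines)]
      body <- body[nchar(body) >= 17]
      resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
      keep <- !is.na(resno)  # chain-break separators have '!' here
      body <- body[keep]
      cd <- substr(body, 17, 17)
      tibble::tibble(
        chain = trimws(substr(body, 12, 12)),
        resno = resno[keep],
        code = ifelse(trimws(cd) == "", "X", cd)
      )
    },
    stride = {
      lines <- grep("^ASG", readLines(path, warn = FALSE), value = TRUE)
      if (length(lines) == 0L) stop("not STRIDE output: no ASG records", call. = FALSE)
      parts <- strsplit(trimws(lines), "\\s+")
      tibble::tibble(
        chain = vapply(parts, `[`, character(1), 3L),
        resno = as.integer(vapply(parts, `[`, character(1), 4L)),
        code = toupper(vapply(parts, `[`, character(1), 6L))
      )
    })
  out$code[out$code == "-"] <- "X"
  bad <- setdiff(unique(out$code), ss_alphabet())
  if (length(bad) > 0L) {
    stop("unknown secondary-structure code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Attach labels to per-residue records
#'
#' Left-joins labels on `(chain, resno)`. Residues without a label get
#' `X`, with a warning naming how many.
#'
#' @param records per-residue tibble with `chain`, `resno`.
#' @param labels tibble from [read_ss_labels()].
#' @return `records` with a `label` column.
#' @export
attach_labels <- function(records, labels) {
  m <- match(paste(records$chain, records$resno),
             paste(labels$chain, labels$resno))
  lab <- labels$code[m]
  n_missing <- sum(is.na(lab))
  if (n_missing > 0L) {
    warning(n_missing, " residue(s) without a label; marked X", call. = FALSE)
    lab[is.na(lab)] <- "X"
  }
  records$label <- lab
  records
}
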