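# Variable selection and vertex/antivertex discretization.

#' Select the analysis variables from a cohort table
#'
#' Drops the patient identifier, the indicators judged redundant
#' (Troponin, PAS, PAD, PAPS), the clinical prediction rules already
#' computed by clinicians (Wells, Revised Geneva, Wicki scores), and
#' holds out `Final diagnosis` as the label. On the full 28-column
#' schema this retains exactly 19 clinical variables.
#'
#' @param cohort Cohort data frame (see [generate_cohort()] /
#'   [read_cohort_csv()]).
#' @param allow_unknown Logical; unknown columns are always reported with
#'   a warning, and retained as features only if this is `TRUE`.
#' @return Character vector of retained variable names, in schema order.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 20, seed = 1))
#' select_variables(cohort)
select_variables <- function(cohort, allow_unknown = FALSE) {
  schema <- cohort_schema()
  cols <- names(cohort)
  unknown <- setdiff(cols, schema$name)
  if (length(unknown)) {
    warning("unknown columns ", paste(unknown, collapse = ", "),
            if (allow_unknown) " retained as features" else " ignored")
  }
  wanted <- schema$name[schema$role == "feature"]
  absent <- setdiff(wanted, cols)
  if (length(absent)) {
    warning("schema feature columns absent from cohort: ",
            paste(absent, collapse = ", "))
  }
  kept <- wanted[wanted %in% cols]
  if (allow_unknown) kept <- c(kept, unknown)
  kept
}

range_hit <- function(x, lo, lo_open, hi, hi_open) {
  !is.na(x) &
    (if (lo_open) x > lo else x >= lo) &
    (if (hi_open) x < hi else x <= hi)
}

#' Discretize a clinical value into a vertex/antivertex pair
#'
#' Applies the threshold map: a value in the `V[0]` range gives
#' `c(anti = TRUE, pos = FALSE)`, a value in the `V[1]` range gives
#' `c(anti = FALSE, pos = TRUE)`, and a missing value gives
#' `c(FALSE, FALSE)` -- the explicit "no information" encoding that the
#' augmented vertex set exists for. A non-missing value covered by
#' neither range (a gap value, e.g. FC < 50 or pH < 7.3) also maps to
#' `c(FALSE, FALSE)` and raises a warning.
#'
#' @param value Numeric (or 0/1) value, `NA` for missing.
#' @param variable Variable name; must appear in `map`.
#' @param map Threshold map, default [default_threshold_map()].
#' @return Named logical vector `c(anti = , pos = )`; never both `TRUE`.
#' @export
#' @examples
#' discretize(70, "Age")    # Age[1]
#' discretize(230, "dDimer") # dDimer[0]: 230 is inside the low-risk range
#' discretize(NA, "Cough")   # <0,0>
discretize <- function(value, variable, map = default_threshold_map()) {
  i <- match(variable, map$variable)
  if (is.na(i)) stop("no threshold map entry for variable: ", variable)
  if (is.na(value)) return(c(anti = FALSE, pos = FALSE))
  anti <- range_hit(value, map$anti_min[i], map$anti_min_open[i],
                    map$anti_max[i], map$anti_max_open[i])
  pos <- range_hit(value, map$pos_min[i], map$pos_min_open[i],
                   map$pos_max[i], map$pos_max_open[i])
  if (anti && pos) pos <- FALSE   # overlap resolved in the map; belt-and-braces
  if (!anti && !pos) {
    warning("value ", value, " for ", variable,
            " falls in a gap of the threshold map; encoded <0,0>")
  }
  c(anti = anti, pos = pos)
}

# Vectorized discretization of one column; a single warning summarises
# gap values. Returns an n x 2 logical matrix (anti, pos).
discretize_column <- function(values, variable, map = default_threshold_map(),
                              warn_gaps = TRUE) {
  i <- match(variable, map$variable)
  if (is.na(i)) stop("no threshold map entry for variable: ", variable)
  values <- as.numeric(values)
  anti <- range_hit(values, map$anti_min[i], map$anti_min_open[i],
                    map$anti_max[i], map$anti_max_open[i])
  pos <- range_hit(values, map$pos_min[i], map$pos_min_open[i],
                   map$pos_max[i], map$pos_max_open[i])
  pos[anti & pos] <- FALSE
  gap <- !is.na(values) & !anti & !pos
  if (warn_gaps && any(gap)) {
    warning(sum(gap), " value(s) of ", variable,
            " fall in a gap of the threshold map; encoded <0,0>")
  }
  cbind(anti = anti, pos = pos)
}

#' Build the augmented incidence matrix
#'
#' Thresholds each requested variable into its descriptor pair and stacks
#' the pairs into a boolean patients x descriptors matrix, the incidence
#' relation that Q-analysis operates on. Column order follows `variables`
#' (each contributing `V[0]` then `V[1]`), so passing the 19 retained
#' variables yields 38 descriptor columns; append `"Final diagnosis"` to
#' obtain the Q-analysis view in which the diagnosis descriptors are
#' ordinary vertices of the complex.
#'
#' The label vector is read from `Final diagnosis` when that column is
#' present; patients with a missing label keep their matrix row (they
#' still shape the backcloth) and carry `NA` in `labels`.
#'
#' @param cohort Cohort data frame.
#' @param variables Variables to threshold; default [select_variables()].
#' @param map Threshold map.
#' @param warn_gaps Emit per-variable gap warnings (see [discretize()]).
#' @return An object of class `augmented_incidence`: list with `matrix`
#'   (0/1 integer), `patients`, `descriptors`, `labels`, and `gap_counts`
#'   (per-variable count of gap-encoded values).
#' @export
build_incidence <- function(cohort, variables = select_variables(cohort),
                            map = default_threshold_map(), warn_gaps = TRUE) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  absent <- setdiff(variables, names(cohort))
  if (length(absent)) stop("variables not in cohort: ", paste(absent, collapse = ", "))
  patients <- if ("ID" %in% names(cohort)) as.character(cohort$ID) else
    sprintf("P%04d", seq_len(nrow(cohort)))
  cols <- vector("list", length(variables))
  gaps <- integer(length(variables))
  names(gaps) <- variables
  for (i in seq_along(variables)) {
    v <- variables[i]
    d <- discretize_column(cohort[[v]], v, map, warn_gaps = warn_gaps)
    gaps[i] <- sum(!is.na(as.numeric(cohort[[v]])) & !d[, 1] & !d[, 2])
    cols[[i]] <- d
  }
  M <- do.call(cbind, cols)
  storage.mode(M) <- "integer"
  dimnames(M) <- list(patients, descriptor_names(variables))
  labels <- if ("Final diagnosis" %in% names(cohort))
    as.integer(cohort[["Final diagnosis"]]) else rep(NA_integer_, nrow(cohort))
  structure(list(matrix = M, patients = patients,
                 descriptors = colnames(M), labels = labels,
                 gap_counts = gaps),
            class = "augmented_incidence")
}

#' @export
print.augmented_incidence <- function(x, ...) {
  cat("Augmented incidence:", nrow(x$matrix), "patients x",
      ncol(x$matrix), "descriptors\n")
  cat("  labelled patients:", sum(!is.na(x$labels)),
      sprintf("(%d positive)\n", sum(x$labels == 1L, na.rm = TRUE)))
  if (sum(x$gap_counts) > 0)
    cat("  gap-encoded values:", sum(x$gap_counts), "\n")
  invisible(x)
}

#' Classifier feature matrix from an incidence object
#'
#' Restricts an augmented incidence to a chosen descriptor set, drops the
#' diagnosis descriptors (the label is never a feature), and drops
#' patients with a missing label.
#'
#' @param incidence An `augmented_incidence`.
#' @param descriptors Descriptor names to keep; default all non-diagnosis
#'   descriptors.
#' @return List with `X` (0/1 matrix), `y` (0/1 integer labels) and
#'   `patients`.
#' @export
feature_matrix <- function(incidence,
                           descriptors = setdiff(incidence$descriptors,
                                                 diagnosis_descriptors())) {
  descriptors <- setdiff(descriptors, diagnosis_descriptors())
  bad <- setdiff(descriptors, incidence$descriptors)
  if (length(bad)) stop("unknown descriptors: ", paste(bad, collapse = ", "))
  keep <- !is.na(incidence$labels)
  list(X = incidence$matrix[keep, descriptors, drop = FALSE],
       y = incidence$labels[keep],
       patients = incidence$patients[keep])
}

#' Cohort and incidence CSV input/output
#'
#' Cohorts are written as comma-separated tables with a header row and
#' the literal string `NaN` for missing entries; incidence matrices as
#' 0/1 integer tables with descriptor-name headers and patient ids in the
#' first column.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return Readers return the object; writers return `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "NaN")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  utils::read.csv(path, check.names = FALSE, na.strings = c("NaN", "NA"),
                  stringsAsFactors = FALSE)
}

#' @rdname write_cohort_csv
#' @param incidence An `augmented_incidence`.
#' @export
write_incidence_csv <- function(incidence, path) {
  df <- data.frame(patient = incidence$patients,
                   incidence$matrix,
                   label = incidence$labels,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NaN")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_incidence_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("NaN", "NA"),
                        stringsAsFactors = FALSE)
  desc <- setdiff(names(df), c("patient", "label"))
  M <- as.matrix(df[desc])
  storage.mode(M) <- "integer"
  rownames(M) <- df$patient
  structure(list(matrix = M, patients = as.character(df$patient),
                 descriptors = desc, labels = as.integer(df$label),
                 gap_counts = integer(0)),
            class = "augmented_incidence")
}
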