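# Clinical variable vocabulary and the vertex/antivertex threshold map.
#
# The cohort schema has 28 columns: a patient identifier, 26 clinical
# indicators, and the final diagnosis label. A subset of 19 indicators is
# retained for analysis; each retained variable is split into an
# antivertex descriptor `V[0]` ("observed, not a risk sign") and a vertex
# descriptor `V[1]` ("observed, risk sign"). Missing values map to
# neither descriptor, <0,0>, so "observed absent" stays distinct from
# "not observed".

#' Clinical variable schema
#'
#' Returns the 28-column cohort schema: variable name, role and
#' measurement type. Roles are `"id"` (patient identifier), `"feature"`
#' (retained clinical indicator), `"redundant"` (indicators dropped
#' because they duplicate information carried by other variables or are
#' almost entirely missing), `"score"` (clinical prediction rules --
#' Wells, Revised Geneva, Wicki -- excluded because they already encode a
#' clinician's synthesis) and `"label"` (final diagnosis).
#'
#' @return A data frame with columns `name`, `role`, `type`.
#' @export
#' @examples
#' schema <- cohort_schema()
#' table(schema$role)
cohort_schema <- function() {
  s <- function(name, role, type) data.frame(name = name, role = role, type = type)
  rbind(
    s("ID",                  "id",        "id"),
    s("Age",                 "feature",   "continuous"),
    s("N_F_Pred",            "feature",   "count"),
    s("N_F_Risk",            "feature",   "count"),
    s("Previous DVT",        "feature",   "boolean"),
    s("Palpitations",        "feature",   "boolean"),
    s("Cough",               "feature",   "boolean"),
    s("dDimer",              "feature",   "continuous"),
    s("PAS",                 "redundant", "continuous"),
    s("PAD",                 "redundant", "continuous"),
    s("FC",                  "feature",   "continuous"),
    s("PAPS",                "redundant", "continuous"),
    s("WBC",                 "feature",   "continuous"),
    s("Cancer at diagnosis", "feature",   "boolean"),
    s("Troponin",            "redundant", "continuous"),
    s("Shockindex",          "feature",   "continuous"),
    s("Cancer",              "feature",   "boolean"),
    s("RVD",                 "feature",   "boolean"),
    s("Wells score",         "score",     "continuous"),
    s("Revised Geneva score","score",     "continuous"),
    s("Wicki score",         "score",     "continuous"),
    s("Dyspnea",             "feature",   "boolean"),
    s("Chest pain",          "feature",   "boolean"),
    s("PCO2",                "feature",   "continuous"),
    s("PO2",                 "feature",   "continuous"),
    s("PH",                  "feature",   "continuous"),
    s("Hemoptysis",          "feature",   "boolean"),
    s("Final diagnosis",     "label",     "boolean")
  )
}

#' Default vertex/antivertex threshold map
#'
#' One row per thresholdable variable, defining the value range mapped to
#' the antivertex descriptor `V[0]` and the range mapped to the vertex
#' descriptor `V[1]`. Ranges are closed intervals `[min, max]` unless the
#' corresponding `_open` flag makes the bound strict. Values falling in
#' neither range (e.g. a heart rate below 50, a pH below 7.3) carry no
#' usable risk information under the map and are encoded <0,0> like
#' missing values, with a warning.
#'
#' The map covers the 19 retained clinical variables plus
#' `Final diagnosis` (whose descriptor pair participates in Q-analysis
#' only, never as a classifier input). WBC ranges meet at exactly 10000;
#' the boundary is assigned to the risk descriptor `WBC[1]`.
#'
#' @param invert_po2 Logical; the printed map marks high PO2 (> 60) as the
#'   risk descriptor `PO2[1]`. Set `TRUE` to invert the pair, reflecting
#'   the clinical reading that hypoxaemia is the risk sign.
#' @return Data frame with columns `variable`, `anti_min`, `anti_min_open`,
#'   `anti_max`, `anti_max_open`, `pos_min`, `pos_min_open`, `pos_max`,
#'   `pos_max_open`.
#' @seealso [discretize()], [read_threshold_map()]
#' @export
default_threshold_map <- function(invert_po2 = FALSE) {
  r <- function(variable, anti_min, anti_max, pos_min, pos_max,
                anti_min_open = FALSE, anti_max_open = FALSE,
                pos_min_open = FALSE, pos_max_open = FALSE) {
    data.frame(variable = variable,
               anti_min = anti_min, anti_min_open = anti_min_open,
               anti_max = anti_max, anti_max_open = anti_max_open,
               pos_min = pos_min, pos_min_open = pos_min_open,
               pos_max = pos_max, pos_max_open = pos_max_open)
  }
  b <- function(variable) r(variable, 0, 0, 1, 1)   # boolean 0/1 indicator
  m <- rbind(
    r("Age",        -Inf,   64,    65,  Inf),
    r("N_F_Pred",      0,    0,     1,  Inf),
    r("N_F_Risk",      0,    0,     1,  Inf),
    b("Previous DVT"),
    b("Palpitations"),
    b("Cough"),
    r("dDimer",     -Inf,  230,   230,  Inf, pos_min_open = TRUE),
    r("FC",           50,   99,   100,  Inf),
    r("WBC",        2000, 10000, 10000, Inf, anti_max_open = TRUE),
    b("Cancer at diagnosis"),
    r("Shockindex",    0, 0.89,   0.9,  Inf),
    b("Cancer"),
    b("RVD"),
    b("Dyspnea"),
    b("Chest pain"),
    r("PCO2",         35,   45,    45,  Inf, pos_min_open = TRUE),
    r("PO2",        -Inf,   60,    60,  Inf, pos_min_open = TRUE),
    r("PH",          7.3, 7.42,  7.42,  Inf, pos_min_open = TRUE),
    b("Hemoptysis"),
    b("Final diagnosis")
  )
  if (invert_po2) {
    i <- m$variable == "PO2"
    m[i, c("anti_min", "anti_min_open", "anti_max", "anti_max_open",
           "pos_min", "pos_min_open", "pos_max", "pos_max_open")] <-
      m[i, c("pos_min", "pos_min_open", "pos_max", "pos_max_open",
             "anti_min", "anti_min_open", "anti_max", "anti_max_open")]
  }
  m
}

#' Read or write a threshold map as CSV
#'
#' The threshold map is data, not code: it can be edited and reloaded.
#' A copy of the default map ships in
#' `system.file("extdata", "threshold_map.csv", package = "neuralhypernet")`.
#'
#' @param path CSV file path.
#' @return `read_threshold_map()` returns the map data frame;
#'   `write_threshold_map()` returns `path` invisibly.
#' @export
read_threshold_map <- function(path) {
  if (!file.exists(path)) stop("threshold map file not found: ", path)
  m <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("variable", "anti_min", "anti_min_open", "anti_max", "anti_max_open",
            "pos_min", "pos_min_open", "pos_max", "pos_max_open")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("threshold map is missing columns: ", paste(miss, collapse = ", "))
  for (cl in grep("_open$", need, value = TRUE)) m[[cl]] <- as.logical(m[[cl]])
  m[need]
}

#' @rdname read_threshold_map
#' @param map Threshold map data frame.
#' @export
write_threshold_map <- function(map, path) {
  utils::write.csv(map, path, row.names = FALSE)
  invisible(path)
}

#' Descriptor names for a set of variables
#'
#' Each variable `V` contributes the ordered pair `V[0]` (antivertex),
#' `V[1]` (vertex).
#'
#' @param variables Character vector of variable names.
#' @return Character vector of length `2 * length(variables)`.
#' @export
descriptor_names <- function(variables) {
  as.vector(rbind(paste0(variables, "[0]"), paste0(variables, "[1]")))
}

# Variable a descriptor name belongs to ("Age[1]" -> "Age").
descriptor_variable <- function(descriptors) {
  sub("\\[[01]\\]$", "", descriptors)
}

# The two diagnosis descriptors, used by Q-analysis but never as features.
diagnosis_descriptors <- function() descriptor_names("Final diagnosis")
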