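#' Construct a path model from an edge table
#'
#' Low-level [SemModel-class] constructor. `edges` is a data.frame with
#' columns `matrix` ("A", "S" or "M"), `from`, `to`, and either a numeric
#' `value` (fixed entry, or start value when a `label` is present) or a
#' character `label` (free parameter; shared labels are equality-constrained).
#' For "A", `from` is the tail (predictor/latent) and `to` the head
#' (outcome/indicator); for "M", `to` names the variable. Unlisted entries
#' are fixed at zero.
#'
#' @param variables character vector of all variable names.
#' @param observed character vector of manifest variable names.
#' @param edges data.frame as described above.
#' @param meta optional list of metadata (e.g. `report` labels).
#' @return A [SemModel-class].
#' @export
semModel <- function(variables, observed, edges, meta = list()) {
  n <- length(variables)
  A <- S <- matrix(0, n, n, dimnames = list(variables, variables))
  Alab <- Slab <- matrix(NA_character_, n, n, dimnames = list(variables, variables))
  M <- stats::setNames(numeric(n), variables)
  Mlab <- stats::setNames(rep(NA_character_, n), variables)
  if (!all(c("matrix", "from", "to") %in% names(edges))) {
    stop("edges must have columns matrix, from, to")
  }
  if (is.null(edges$value)) edges$value <- NA_real_
  if (is.null(edges$label)) edges$label <- NA_character_
  for (k in seq_len(nrow(edges))) {
    e <- edges[k, ]
    bad <- setdiff(stats::na.omit(c(e$from, e$to)), variables)
    if (length(bad)) stop("unknown variable in edge table: ", paste(bad, collapse = ", "))
    val <- if (is.na(e$value)) 0 else e$value
    if (e$matrix == "A") {
      A[e$to, e$from] <- val
      if (!is.na(e$label)) Alab[e$to, e$from] <- e$label
    } else if (e$matrix == "S") {
      S[e$to, e$from] <- S[e$from, e$to] <- val
      if (!is.na(e$label)) Slab[e$to, e$from] <- Slab[e$from, e$to] <- e$label
    } else if (e$matrix == "M") {
      M[e$to] <- val
      if (!is.na(e$label)) Mlab[e$to] <- e$label
    } else stop("edge matrix must be one of A, S, M")
  }
  methods::new("SemModel",
    variables = variables, observed = observed,
    A = A, S = S, M = M, Alab = Alab, Slab = Slab, Mlab = Mlab,
    meta = meta)
}

#' @describeIn semModel variable names of a model.
#' @param model a [SemModel-class].
#' @export
semVariables <- function(model) model@variables

#' @describeIn semModel manifest (observed) variable names.
#' @export
semObserved <- function(model) model@observed

#' Free-parameter table of a path model
#'
#' One row per free entry (label, matrix, row/column indices). Labels are
#' ordered by first appearance; symmetric `S` entries appear once per
#' unordered pair.
#'
#' @param model a [SemModel-class].
#' @return data.frame with columns `label`, `matrix`, `row`, `col`.
#' @export
freeParamTable <- function(model) {
  out <- list()
  n <- length(model@variables)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!is.na(model@Alab[i, j])) {
      out[[length(out) + 1L]] <- data.frame(
        label = model@Alab[i, j], matrix = "A", row = i, col = j)
    }
  }
  for (i in seq_len(n)) for (j in seq_len(i)) {
    if (!is.na(model@Slab[i, j])) {
      out[[length(out) + 1L]] <- data.frame(
        label = model@Slab[i, j], matrix = "S", row = i, col = j)
    }
  }
  for (i in seq_len(n)) {
    if (!is.na(model@Mlab[i])) {
      out[[length(out) + 1L]] <- data.frame(
        label = model@Mlab[i], matrix = "M", row = i, col = NA_integer_)
    }
  }
  if (!length(out)) {
    return(data.frame(label = character(0), matrix = character(0),
                      row = integer(0), col = integer(0)))
  }
  tab <- do.call(rbind, out)
  tab$label <- as.character(tab$label)
  tab[order(match(tab$label, unique(tab$label))), , drop = FALSE]
}

semLabels <- function(model) unique(freeParamTable(model)$label)

# Write a parameter vector (named by label, or positional in label order)
# into the model matrices; returns the updated model.
applyTheta <- function(model, theta) {
  tab <- freeParamTable(model)
  labs <- unique(tab$label)
  if (is.null(names(theta))) {
    if (length(theta) != length(labs)) stop("theta length must equal number of free labels")
    theta <- stats::setNames(theta, labs)
  }
  missing <- setdiff(labs, names(theta))
  if (length(missing)) stop("theta missing labels: ", paste(missing, collapse = ", "))
  for (k in seq_len(nrow(tab))) {
    v <- theta[[tab$label[k]]]
    if (tab$matrix[k] == "A") {
      model@A[tab$row[k], tab$col[k]] <- v
    } else if (tab$matrix[k] == "S") {
      model@S[tab$row[k], tab$col[k]] <- v
      model@S[tab$col[k], tab$row[k]] <- v
    } else model@M[tab$row[k]] <- v
  }
  model
}

# Current values of the free parameters as stored in the model matrices.
currentTheta <- function(model) {
  tab <- freeParamTable(model)
  labs <- unique(tab$label)
  vapply(labs, function(l) {
    r <- tab[tab$label == l, ][1, ]
    switch(r$matrix,
      A = model@A[r$row, r$col],
      S = model@S[r$row, r$col],
      M = model@M[r$row])
  }, numeric(1))
}

#' @export
setMethod("show", "SemModel", function(object) {
  tab <- freeParamTable(object)
  cat(sprintf("SemModel: %d variables (%d observed, %d latent), %d free parameters (%d labels)\n",
              length(object@variables), length(object@observed),
              length(object@variables) - length(object@observed),
              nrow(tab), length(unique(tab$label))))
  if (!is.null(object@meta$report)) {
    cat("  reserved report labels:", paste(unlist(object@meta$report), collapse = ", "), "\n")
  }
  invisible(object)
})

#' Serialize a path model to JSON
#'
#' The JSON dialect is a list of entries `{matrix, from, to, value|label}`
#' plus the variable/observed name vectors; [readSemModel()] restores the
#' model losslessly.
#'
#' @param model a [SemModel-class].
#' @param path file path; if `NULL`, the JSON string is returned.
#' @export
writeSemModel <- function(model, path = NULL) {
  n <- length(model@variables)
  ent <- list()
  add <- function(mat, from, to, value, label) {
    ent[[length(ent) + 1L]] <<- list(matrix = mat, from = from, to = to,
                                     value = value, label = label)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (model@A[i, j] != 0 || !is.na(model@Alab[i, j])) {
      add("A", model@variables[j], model@variables[i], model@A[i, j], model@Alab[i, j])
    }
  }
  for (i in seq_len(n)) for (j in seq_len(i)) {
    if (model@S[i, j] != 0 || !is.na(model@Slab[i, j])) {
      add("S", model@variables[j], model@variables[i], model@S[i, j], model@Slab[i, j])
    }
  }
  for (i in seq_len(n)) {
    if (model@M[i] != 0 || !is.na(model@Mlab[i])) {
      add("M", NA_character_, model@variables[i], model@M[i], model@Mlab[i])
    }
  }
  obj <- list(variables = model@variables, observed = model@observed,
              meta = model@meta, edges = ent)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @describeIn writeSemModel read a model back from JSON (path or string).
#' @param x a file path or JSON string produced by [writeSemModel()].
#' @export
readSemModel <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  edges <- obj$edges
  if (is.null(edges$label)) edges$label <- NA_character_
  edges$label <- as.character(edges$label)
  edges$value <- as.numeric(edges$value)
  meta <- obj$meta %||% list()
  semModel(obj$variables, obj$observed, edges, meta = as.list(meta))
}
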