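#' Baseline connectivity graph of the seven-region network
#'
#' Bidirectional coupling within the execution-related set (S/M1, IPL, PMv,
#' aIPS) and within the observation-related set (pSTS, IPL, aIPS, MT/V5),
#' plus the visual feed-forward edge OP -> MT/V5. The PMv-pSTS pair is
#' excluded here: its presence and direction is the model-space attribute
#' varied across candidate models. The driving (task) input always enters OP,
#' which receives no edges.
#'
#' @return data.frame with columns `from`, `to` (23 directed edges).
#' @export
base_graph <- function() {
  exec_set <- c("S/M1", "IPL", "PMv", "aIPS")
  obs_set <- c("pSTS", "IPL", "aIPS", "MT/V5")
  bidir <- function(set) {
    g <- expand.grid(from = set, to = set, stringsAsFactors = FALSE)
    g[g$from != g$to, ]
  }
  edges <- rbind(bidir(exec_set), bidir(obs_set),
                 data.frame(from = "OP", to = "MT/V5"))
  edges <- unique(edges)
  rownames(edges) <- NULL
  edges[order(match(edges$to, region_names()), match(edges$from, region_names())), ,
        drop = FALSE] -> edges
  rownames(edges) <- NULL
  edges
}

.conn_patterns <- c("mutual", "pmv_to_psts", "psts_to_pmv", "none")
.input_patterns <- c("dual", "pmv_only", "psts_only", "none")

.pmv_psts_edges <- function(pattern) {
  switch(pattern,
    mutual = data.frame(from = c("PMv", "pSTS"), to = c("pSTS", "PMv")),
    pmv_to_psts = data.frame(from = "PMv", to = "pSTS"),
    psts_to_pmv = data.frame(from = "pSTS", to = "PMv"),
    none = data.frame(from = character(0), to = character(0)),
    stop("unknown connection pattern")
  )
}

.extra_inputs <- function(pattern) {
  switch(pattern,
    dual = data.frame(input = c("exec", "hand"), region = c("PMv", "pSTS")),
    pmv_only = data.frame(input = "exec", region = "PMv"),
    psts_only = data.frame(input = "hand", region = "pSTS"),
    none = data.frame(input = character(0), region = character(0)),
    stop("unknown input pattern")
  )
}

#' Construct one candidate model specification
#'
#' @param conn_pattern PMv-pSTS baseline connectivity: one of "mutual",
#'   "pmv_to_psts", "psts_to_pmv", "none".
#' @param input_pattern Extra driving inputs: "dual" (Execution -> PMv and
#'   Hand -> pSTS), "pmv_only", "psts_only", "none". The task cue input to OP
#'   is present in every model.
#' @return Object of class `dcm_model`: `id`, the two pattern labels,
#'   `a_edges` (data.frame from/to), `b_edges` (list exec/hand; both factors
#'   modulate every baseline edge of the model), `c_inputs` (data.frame
#'   input/region), `regions`.
#' @export
model_spec <- function(conn_pattern = "mutual", input_pattern = "dual") {
  conn_pattern <- match.arg(conn_pattern, .conn_patterns)
  input_pattern <- match.arg(input_pattern, .input_patterns)
  a_edges <- rbind(base_graph(), .pmv_psts_edges(conn_pattern))
  rownames(a_edges) <- NULL
  c_inputs <- rbind(data.frame(input = "task", region = "OP"),
                    .extra_inputs(input_pattern))
  ci <- match(conn_pattern, .conn_patterns)
  ii <- match(input_pattern, .input_patterns)
  out <- list(
    id = as.integer(4L * (ci - 1L) + ii),
    conn_pattern = conn_pattern,
    input_pattern = input_pattern,
    regions = region_names(),
    a_edges = a_edges,
    b_edges = list(exec = a_edges, hand = a_edges),
    c_inputs = c_inputs
  )
  class(out) <- "dcm_model"
  out
}

#' Enumerate the sixteen-model space
#'
#' The full crossing of 4 PMv-pSTS connectivity patterns by 4 extra-input
#' patterns. Model 1 is the mutual-connection, dual-input model; ids run
#' row-major over (connection pattern x input pattern).
#'
#' @return List of 16 `dcm_model` objects, element i having `id == i`.
#' @export
enumerate_models <- function() {
  out <- vector("list", 16L)
  for (cp in .conn_patterns) {
    for (ip in .input_patterns) {
      m <- model_spec(cp, ip)
      out[[m$id]] <- m
    }
  }
  out
}

#' Family partitions of the model space
#'
#' Two orthogonal partitions of the 16 models into 4 families each: by the
#' pattern of extra driving inputs, and by the PMv-pSTS baseline connectivity
#' pattern.
#'
#' @return Named list of two `family_partition` objects (`input`,
#'   `connection`), each with `name` and `assignment` (character vector,
#'   names "1".."16").
#' @export
partitions <- function() {
  models <- enumerate_models()
  mk <- function(name, field) {
    assignment <- vapply(models, function(m) m[[field]], character(1))
    names(assignment) <- vapply(models, function(m) as.character(m$id), character(1))
    structure(list(name = name, assignment = assignment),
              class = "family_partition")
  }
  list(input = mk("input", "input_pattern"),
       connection = mk("connection", "conn_pattern"))
}

# n x n logical mask (rows = to, cols = from) from an edge data.frame.
edge_mask <- function(edges, regions = region_names()) {
  mask <- matrix(FALSE, length(regions), length(regions),
                 dimnames = list(to = regions, from = regions))
  if (nrow(edges)) {
    mask[cbind(match(edges$to, regions), match(edges$from, regions))] <- TRUE
  }
  mask
}

#' Number of free coupling parameters in a model
#' @param model A `dcm_model`.
#' @return Integer: enabled A edges + enabled B entries (both factors) +
#'   enabled C entries.
#' @export
n_free_parameters <- function(model) {
  nrow(model$a_edges) + sum(vapply(model$b_edges, nrow, integer(1))) +
    nrow(model$c_inputs)
}

#' @export
print.dcm_model <- function(x, ...) {
  cat("DCM model ", x$id, ": PMv-pSTS '", x$conn_pattern, "', inputs '",
      x$input_pattern, "' (", nrow(x$a_edges), " A edges, ",
      n_free_parameters(x), " free parameters)\n", sep = "")
  invisible(x)
}

#' Serialize a model space to JSON
#' @param models List of `dcm_model` objects.
#' @param path Output path.
#' @export
write_model_space <- function(models, path) {
  payload <- lapply(models, function(m) {
    list(id = m$id, conn_pattern = m$conn_pattern,
         input_pattern = m$input_pattern,
         a_edges = m$a_edges, c_inputs = m$c_inputs)
  })
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model space back from JSON
#' @param path JSON path written by [write_model_space()].
#' @return List of `dcm_model` objects.
#' @export
read_model_space <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  lapply(seq_len(nrow(payload)), function(i) {
    model_spec(payload$conn_pattern[i], payload$input_pattern[i])
  })
}

#' GraphViz dot export of one model
#' @param model A `dcm_model`.
#' @return Character scalar with dot source.
#' @export
model_to_dot <- function(model) {
  q <- function(x) paste0('"', x, '"')
  lines <- c("digraph dcm {",
             paste0("  ", q(model$a_edges$from), " -> ", q(model$a_edges$to), ";"),
             paste0("  ", q(model$c_inputs$input), " -> ",
                    q(model$c_inputs$region), " [style=dashed];"),
             "}")
  paste(lines, collapse = "\n")
}
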