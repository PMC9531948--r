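#' Clinical similarity configuration
#'
#' Parameterizes the four-component clinical similarity score between two
#' patients:
#' \describe{
#'   \item{demographics}{`same-sex * w_sex + age_kernel(|age_a - age_b|) *
#'     w_age`, where the age kernel gives full credit up to
#'     `age_full_years`, half credit up to `age_half_years`, and zero
#'     beyond.}
#'   \item{location}{1 if the tumour lobes match, else 0.}
#'   \item{histology}{1 if the histologies match, else 0.}
#'   \item{stage}{1 if the pathological sub-stages (IA/IB/IIA/IIB) match,
#'     else 0.}
#' }
#' Component scores are combined by `rule`: `"sum"` (default; range
#' `[0, w_sex + w_age + 3]`) or `"product"` (any zero component removes the
#' edge). Patients are connected when the combined score reaches
#' `threshold`, and the score becomes the edge weight. The sum rule with
#' threshold 2 keeps patients connected when they agree on roughly two of
#' the four clinical axes, and yields edge weights on the 0-5 scale on
#' which neighbour-median values in the 2-3 range are meaningful.
#'
#' @param rule `"sum"` or `"product"`.
#' @param threshold minimum combined score for an edge.
#' @param w_sex,w_age weights of the two demographic terms.
#' @param age_full_years,age_half_years age-kernel breakpoints (years).
#' @return object of class `similarity_config`.
#' @export
similarity_config <- function(rule = c("sum", "product"), threshold = 2.0,
                              w_sex = 1, w_age = 1,
                              age_full_years = 5, age_half_years = 10) {
  rule <- match.arg(rule)
  if (age_full_years > age_half_years)
    stop("age_full_years must not exceed age_half_years")
  if (threshold < 0) stop("threshold must be non-negative")
  structure(list(rule = rule, threshold = threshold, w_sex = w_sex,
                 w_age = w_age, age_full_years = age_full_years,
                 age_half_years = age_half_years),
            class = "similarity_config")
}

age_kernel <- function(gap, cfg) {
  ifelse(gap <= cfg$age_full_years, 1,
         ifelse(gap <= cfg$age_half_years, 0.5, 0))
}

#' Component similarity scores for a pair of patients
#'
#' @param a,b single patient records (one-row data.frames or lists with
#'   fields `age`, `sex`, `histology`, `lobe`, `stage`).
#' @param cfg a [similarity_config()].
#' @return named numeric vector
#'   `c(demographics, location, histology, stage)`.
#' @export
component_scores <- function(a, b, cfg = similarity_config()) {
  demo <- (a$sex == b$sex) * cfg$w_sex +
    age_kernel(abs(a$age - b$age), cfg) * cfg$w_age
  c(demographics = as.numeric(demo),
    location = as.numeric(a$lobe == b$lobe),
    histology = as.numeric(a$histology == b$histology),
    stage = as.numeric(a$stage == b$stage))
}

#' Combined clinical similarity between two patients
#'
#' @inheritParams component_scores
#' @return non-negative scalar; symmetric in its arguments.
#' @export
similarity <- function(a, b, cfg = similarity_config()) {
  s <- component_scores(a, b, cfg)
  if (cfg$rule == "sum") sum(s) else prod(s)
}

# All-pairs similarity matrix, vectorized over the cohort. Diagonal is the
# self-similarity; callers drop it.
similarity_matrix <- function(records, cfg) {
  same <- function(x) {
    xi <- match(x, unique(x))  # integer comparison: much faster than strings
    outer(xi, xi, `==`) * 1
  }
  gap <- abs(outer(records$age, records$age, `-`))
  agek <- (gap <= cfg$age_full_years) * 1 +
    (gap > cfg$age_full_years & gap <= cfg$age_half_years) * 0.5
  demo <- same(records$sex) * cfg$w_sex + agek * cfg$w_age
  comp <- list(demo, same(records$lobe), same(records$histology),
               same(records$stage))
  if (cfg$rule == "sum") Reduce(`+`, comp) else Reduce(`*`, comp)
}

#' Build the patient population graph
#'
#' Nodes are patients (ordered by id); an undirected edge connects two
#' patients whenever their combined clinical similarity reaches
#' `cfg$threshold`, with the similarity as edge weight. Node features and
#' train/val/test masks are attached.
#'
#' @param records data.frame of patient records; must contain a `split`
#'   column (see [assign_splits()]).
#' @param features numeric matrix with one row per record (aligned by
#'   position; rownames, if present, must match ids).
#' @param cfg a [similarity_config()].
#' @return object of class `population_graph`: list with `node_ids`,
#'   `features`, `edges` (data.frame `i`, `j`, `weight` with `i < j`,
#'   indices into `node_ids`), `masks` (list of logical vectors `train`,
#'   `val`, `test`) and `records`.
#' @export
build_graph <- function(records, features, cfg = similarity_config()) {
  if (anyDuplicated(records$id)) stop("duplicated patient ids")
  if (nrow(features) != nrow(records))
    stop("feature rows must align with records")
  if (!is.null(rownames(features)) &&
      !identical(rownames(features), records$id))
    features <- features[match(records$id, rownames(features)), , drop = FALSE]
  if (is.null(records$split)) stop("records need a 'split' column; see assign_splits()")

  ord <- order(records$id)
  records <- records[ord, , drop = FALSE]
  features <- features[ord, , drop = FALSE]
  n <- nrow(records)

  sim <- similarity_matrix(records, cfg)
  keep <- which(upper.tri(sim) & sim >= cfg$threshold, arr.ind = TRUE)
  edges <- data.frame(i = keep[, 1], j = keep[, 2],
                      weight = sim[keep])

  masks <- lapply(c(train = "train", val = "val", test = "test"),
                  function(s) records$split == s)
  structure(list(node_ids = records$id, features = features, edges = edges,
                 masks = masks, records = records),
            class = "population_graph")
}

#' @export
print.population_graph <- function(x, ...) {
  n <- length(x$node_ids)
  cat(sprintf(
    "Population graph: %d patients, %d edges (mean degree %.1f), %d features\n",
    n, nrow(x$edges), 2 * nrow(x$edges) / max(n, 1), ncol(x$features)))
  cat(sprintf("  split: %d train / %d val / %d test\n",
              sum(x$masks$train), sum(x$masks$val), sum(x$masks$test)))
  invisible(x)
}

# Sparse symmetric weighted adjacency of a population graph.
adjacency_matrix <- function(g) {
  n <- length(g$node_ids)
  if (nrow(g$edges) == 0L)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n)))
  Matrix::sparseMatrix(i = c(g$edges$i, g$edges$j),
                       j = c(g$edges$j, g$edges$i),
                       x = c(g$edges$weight, g$edges$weight),
                       dims = c(n, n))
}

# Row-normalized adjacency: row v holds w_uv / sum_u w_uv; all-zero rows
# (isolated nodes) stay zero, matching the empty-neighbourhood convention.
normalized_adjacency <- function(g) {
  A <- adjacency_matrix(g)
  rs <- Matrix::rowSums(A)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% A
}

#' Neighbour profile of one patient node
#'
#' Summarizes a node's neighbourhood: neighbour count and the median edge
#' weight separately for high- and low-risk neighbours. Used to inspect
#' whether a patient's risk class is echoed by the clinical similarity of
#' its strongest neighbours.
#'
#' @param g a [build_graph()] result.
#' @param node a patient id present in the graph.
#' @param risk_labels character vector (`"high"`/`"low"`) aligned with
#'   `g$node_ids`, e.g. from [risk_stratify()].
#' @return list with `n_neighbours`, `median_weight_high`,
#'   `median_weight_low` (NA with a flag when a class is absent), and the
#'   per-neighbour table.
#' @export
neighbour_profile <- function(g, node, risk_labels) {
  v <- match(node, g$node_ids)
  if (is.na(v)) stop(sprintf("unknown node '%s'", node))
  stopifnot(length(risk_labels) == length(g$node_ids))
  e <- g$edges
  hit <- e$i == v | e$j == v
  nb <- ifelse(e$i[hit] == v, e$j[hit], e$i[hit])
  w <- e$weight[hit]
  cls <- risk_labels[nb]
  med <- function(k) if (any(cls == k)) stats::median(w[cls == k]) else NA_real_
  list(n_neighbours = length(nb),
       median_weight_high = med("high"),
       median_weight_low = med("low"),
       high_absent = !any(cls == "high"),
       low_absent = !any(cls == "low"),
       neighbours = data.frame(id = g$node_ids[nb], weight = w, risk = cls,
                               stringsAsFactors = FALSE))
}

#' Node-feature correlation with a target node before/after one layer
#'
#' Pearson correlation between a target patient's embedding and each
#' neighbour's, on the raw node features and again after one edge-weighted
#' aggregation layer of a trained model, showing how much of the neighbours'
#' ordering is contributed by the graph update.
#'
#' @param g a population graph.
#' @param model a trained [survival_model] (or `NULL` to use an
#'   untrained identity pass-through on raw features only).
#' @param node target patient id.
#' @return data.frame with neighbour id and correlations `cor_raw`,
#'   `cor_layer1` (NA if no model given).
#' @export
neighbour_feature_correlation <- function(g, model, node) {
  v <- match(node, g$node_ids)
  if (is.na(v)) stop(sprintf("unknown node '%s'", node))
  e <- g$edges
  hit <- e$i == v | e$j == v
  nb <- ifelse(e$i[hit] == v, e$j[hit], e$i[hit])
  cors <- function(H) vapply(nb, function(u)
    suppressWarnings(stats::cor(H[v, ], H[u, ])), numeric(1))
  out <- data.frame(id = g$node_ids[nb], cor_raw = cors(g$features),
                    stringsAsFactors = FALSE)
  out$cor_layer1 <- if (!is.null(model)) {
    A <- normalized_adjacency(g)
    H1 <- sage_layer(g, g$features, model$layer1, A = A)
    cors(H1)
  } else NA_real_
  out
}

#' Write / read a population graph as plain text
#'
#' The edge list goes to a TSV (`id_a`, `id_b`, `weight`), node features to
#' a TSV matrix with ids in the first column, and records to the clinical
#' CSV (see [write_clinical()]).
#'
#' @param g a population graph.
#' @param prefix path prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>_features.tsv`, `<prefix>_clinical.csv`.
#' @return the prefix (write) or a population graph (read), invisibly.
#' @export
write_graph <- function(g, prefix) {
  ed <- data.frame(id_a = g$node_ids[g$edges$i], id_b = g$node_ids[g$edges$j],
                   weight = g$edges$weight)
  utils::write.table(ed, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  feat <- data.frame(id = g$node_ids, g$features, check.names = FALSE)
  utils::write.table(feat, paste0(prefix, "_features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_clinical(g$records, paste0(prefix, "_clinical.csv"))
  invisible(prefix)
}

#' @rdname write_graph
#' @export
read_graph <- function(prefix) {
  records <- read_clinical(paste0(prefix, "_clinical.csv"))
  feat <- utils::read.delim(paste0(prefix, "_features.tsv"),
                            check.names = FALSE)
  features <- as.matrix(feat[, -1, drop = FALSE])
  rownames(features) <- feat$id
  ed <- utils::read.delim(paste0(prefix, "_edges.tsv"))
  i <- match(ed$id_a, records$id)
  j <- match(ed$id_b, records$id)
  sw <- pmin(i, j); j <- pmax(i, j); i <- sw
  g <- structure(list(node_ids = records$id, features = features,
                      edges = data.frame(i = i, j = j, weight = ed$weight),
                      masks = lapply(c(train = "train", val = "val",
                                       test = "test"),
                                     function(s) records$split == s),
                      records = records),
                 class = "population_graph")
  g
}
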