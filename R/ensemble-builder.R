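# Feature-vector compositions: the 16 individual sources (handcrafted
# fractal vector, five CNN embeddings, five Grad-CAM and five LIME fractal
# vectors) and the 39 enumerated ensembles built from them by horizontal
# aggregation.

#' The 16 individual feature sources
#'
#' @return Data frame with `id`, `group` (handcrafted / deep / xai_cam /
#'   xai_lime) and `dim` for every source: F and all xAI vectors carry 116
#'   fractal features; the deep sources carry their architecture's embedding
#'   length (D 1024, E 1408, I 2048, R 2048, V 4096).
#' @export
feature_sources <- function() {
  deep <- c(D = 1024L, E = 1408L, I = 2048L, R = 2048L, V = 4096L)
  data.frame(
    id = c("F", names(deep), paste0(names(deep), "CAM"),
           paste0(names(deep), "LIME")),
    group = c("handcrafted", rep("deep", 5), rep("xai_cam", 5),
              rep("xai_lime", 5)),
    dim = c(116L, unname(deep), rep(116L, 10)),
    stringsAsFactors = FALSE)
}

new_composition <- function(ids, category, sources) {
  dims <- sources$dim[match(ids, sources$id)]
  structure(list(name = paste(ids, collapse = " + "), sources = ids,
                 total_dim = sum(dims), category = category),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("<composition> %s [%s] dim=%d\n", x$name, x$category,
              x$total_dim))
  invisible(x)
}

#' Enumerate the 55 feature-vector compositions
#'
#' 16 singletons; 6 handcrafted+deep ensembles (F with each CNN, plus F with
#' all five); 11 deep ensembles (all 10 pairs plus all five); and 22 xAI
#' ensembles (10 Grad-CAM pairs plus all-CAM, 10 LIME pairs plus all-LIME).
#' Source order within a name is canonical (F, then D E I R V, then the CAM
#' block, then the LIME block), so dimensionalities and column layouts are
#' reproducible.
#'
#' @param sources Data frame as returned by [feature_sources()].
#' @return List of 55 `composition` objects.
#' @examples
#' comps <- enumerate_compositions()
#' length(comps) # 55
#' @export
enumerate_compositions <- function(sources = feature_sources()) {
  required <- feature_sources()$id
  missing <- setdiff(required, sources$id)
  if (length(missing))
    stop("missing feature source(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  deep <- c("D", "E", "I", "R", "V")
  singleton_cat <- c(handcrafted = "handcrafted", deep = "deep",
                     xai_cam = "xai", xai_lime = "xai")
  comps <- lapply(seq_len(nrow(sources)), function(i)
    new_composition(sources$id[i], unname(singleton_cat[sources$group[i]]),
                    sources))

  for (d in deep)
    comps <- c(comps, list(new_composition(c("F", d), "ens_handcrafted_deep",
                                           sources)))
  comps <- c(comps, list(new_composition(c("F", deep), "ens_handcrafted_deep",
                                         sources)))

  pairs <- utils::combn(deep, 2, simplify = FALSE)
  for (p in pairs)
    comps <- c(comps, list(new_composition(p, "ens_deep", sources)))
  comps <- c(comps, list(new_composition(deep, "ens_deep", sources)))

  for (suffix in c("CAM", "LIME")) {
    ids <- paste0(deep, suffix)
    for (p in utils::combn(ids, 2, simplify = FALSE))
      comps <- c(comps, list(new_composition(p, "ens_xai", sources)))
    comps <- c(comps, list(new_composition(ids, "ens_xai", sources)))
  }
  comps
}

#' Composition manifest as a data frame
#'
#' @param compositions List from [enumerate_compositions()].
#' @return Data frame with `name`, `category`, `total_dim`, `n_sources`.
#' @export
composition_manifest <- function(compositions = enumerate_compositions()) {
  data.frame(
    name = vapply(compositions, `[[`, character(1), "name"),
    category = vapply(compositions, `[[`, character(1), "category"),
    total_dim = vapply(compositions, `[[`, integer(1), "total_dim"),
    n_sources = vapply(compositions, function(x) length(x$sources),
                       integer(1)),
    stringsAsFactors = FALSE)
}

#' Concatenate per-source feature tables for a composition
#'
#' Horizontally joins the named feature tables in composition order, matched
#' by `image_id`. Column names are prefixed `<source id>.` so per-source
#' blocks remain recoverable.
#'
#' @param tables Named list of data frames (names are source ids; each table
#'   has an `image_id` column plus feature columns) covering identical image
#'   ids.
#' @param composition A `composition`.
#' @return Data frame with `image_id` plus `total_dim` feature columns.
#' @export
concatenate_features <- function(tables, composition) {
  missing <- setdiff(composition$sources, names(tables))
  if (length(missing))
    stop("missing feature table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ids <- sort(tables[[composition$sources[1]]]$image_id)
  for (s in composition$sources) {
    other <- sort(tables[[s]]$image_id)
    if (!identical(ids, other)) {
      diff <- c(setdiff(ids, other), setdiff(other, ids))
      stop("image-id mismatch across tables: ",
           paste(utils::head(diff, 10), collapse = ", "), call. = FALSE)
    }
  }
  out <- data.frame(image_id = ids, stringsAsFactors = FALSE)
  for (s in composition$sources) {
    tab <- tables[[s]]
    tab <- tab[match(ids, tab$image_id), , drop = FALSE]
    feats <- tab[, setdiff(names(tab), "image_id"), drop = FALSE]
    names(feats) <- paste0(s, ".", names(feats))
    out <- cbind(out, feats)
  }
  rownames(out) <- NULL
  out
}
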