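# ggplot2 views of weight tables, clusterings and predictions.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_col
#'   scale_fill_viridis_c labs theme_minimal coord_fixed
#' @export
ggplot2::autoplot

#' Heatmap of a learned weight table
#'
#' Contrasted edge-type weights laid out as the 20 x 20 residue-type matrix
#' (symmetric; each unordered pair shown twice).
#'
#' @param object Tibble from [weight_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.betop_weights <- function(object, ...) {
  df <- object
  a1 <- substr(df$type, 1, 1)
  a2 <- substr(df$type, 2, 2)
  full <- dplyr::bind_rows(
    tibble::tibble(x = a1, y = a2, weight = df$weight),
    tibble::tibble(x = a2, y = a1, weight = df$weight)
  ) %>% dplyr::distinct()
  ggplot(full, aes(x = .data$x, y = .data$y, fill = .data$weight)) +
    geom_tile() +
    scale_fill_viridis_c(name = "weight") +
    coord_fixed() +
    labs(x = NULL, y = NULL,
         title = "Contrasted residue-pair edge weights") +
    theme_minimal()
}

#' Plot a weight table
#' @param wt Tibble from [weight_table()].
#' @return A ggplot object.
#' @export
plot_weight_table <- function(wt) {
  class(wt) <- c("betop_weights", class(wt))
  autoplot(wt)
}

#' Surface-residue map of a prediction
#'
#' Residues of the antigen surface projected on their first two principal
#' axes, coloured by predicted epitope membership.
#'
#' @param object A `betop_prediction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.betop_prediction <- function(object, ...) {
  nodes <- object$graph$nodes
  xy <- prcomp(as.matrix(nodes[, c("x", "y", "z")]))$x[, 1:2]
  df <- tibble::tibble(
    pc1 = xy[, 1], pc2 = xy[, 2],
    epitope = factor(ifelse(object$residues$predicted,
                            paste("epitope", object$residues$epitope_id),
                            "non-epitope"))
  )
  ggplot(df, aes(x = .data$pc1, y = .data$pc2, colour = .data$epitope)) +
    geom_point(size = 2) +
    coord_fixed() +
    labs(x = "PC1 (A)", y = "PC2 (A)",
         title = "Predicted epitope residues on the antigen surface") +
    theme_minimal()
}

#' Bar chart of per-antigen evaluation metrics
#'
#' @param metrics Tibble with columns `antigen` and `fscore` (e.g. built
#'   from [score_prediction()] results).
#' @return A ggplot object.
#' @export
plot_fscores <- function(metrics) {
  ggplot(metrics, aes(x = factor(.data$antigen), y = .data$fscore)) +
    geom_col(fill = "steelblue") +
    labs(x = "antigen", y = "f-score",
         title = "Per-antigen prediction f-score") +
    theme_minimal()
}
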