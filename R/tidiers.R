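#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted synthesis model
#'
#' One row per parameter with its marginal transform and subsystem, plus
#' the subsystem copula family and implied Kendall tau.
#'
#' @param x A `synthesis_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.synthesis_model <- function(x, ...) {
  sub_of <- rlang::set_names(
    rep(names(x$partition), lengths(x$partition)), unlist(x$partition))
  purrr::map_dfr(sleep_parameters(), function(p) {
    m <- x$marginals[[p]]
    sub <- sub_of[[p]]
    cm <- x$vine$models[[sub]]
    tibble::tibble(parameter = p, subsystem = sub, transform = m$kind,
                   location = m$location, scale = m$scale,
                   family = cm$family,
                   theta = if (is.null(cm$theta)) NA_real_ else cm$theta,
                   implied_tau = implied_tau(cm))
  })
}

#' @rdname tidy.synthesis_model
#' @export
glance.synthesis_model <- function(x, ...) {
  tibble::tibble(
    n_reference = x$n_reference, n_dropped = x$n_dropped,
    family_sub1 = x$vine$models[[1]]$family,
    family_sub2 = x$vine$models[[2]]$family,
    tau_sub1 = implied_tau(x$vine$models[[1]]),
    tau_sub2 = implied_tau(x$vine$models[[2]]),
    link_rho = if (is.null(x$vine$link)) NA_real_ else x$vine$link$rho
  )
}

#' Tidy a fidelity report
#' @param x A `fidelity_report`.
#' @param ... Unused.
#' @return Per-variable tibble of KL and KS results.
#' @export
tidy.fidelity_report <- function(x, ...) x$per_variable

#' @rdname tidy.fidelity_report
#' @export
glance.fidelity_report <- function(x, ...) {
  tibble::tibble(ks_median_p = x$ks_median_p, ks_min_p = x$ks_min_p,
                 kl_mean = mean(x$per_variable$kl),
                 hsic = x$hsic, hsic_p = x$hsic_p, hsic_mode = x$hsic_mode,
                 n_real = x$n_real, n_synth = x$n_synth)
}

#' Tidy a cluster model
#' @param x A `cluster_model`.
#' @param ... Unused.
#' @return Tibble of standardized centroid coordinates per cluster.
#' @export
tidy.cluster_model <- function(x, ...) {
  tibble::as_tibble(x$centroids) |>
    dplyr::mutate(cluster = dplyr::row_number(),
                  archetype = x$archetype, .before = 1)
}

#' @rdname tidy.cluster_model
#' @export
glance.cluster_model <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$cluster),
                 sizes = paste(tabulate(x$cluster, x$k), collapse = "/"))
}

#' Plot per-variable fidelity of a synthetic cohort
#'
#' Bars of the per-variable two-sample KS p-values with the conventional
#' 0.05 reference line, faceted against the per-variable KL divergence.
#'
#' @param object A `fidelity_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fidelity_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_variable,
                            cols = c("kl", "ks_p"),
                            names_to = "metric", values_to = "value")
  df$metric <- dplyr::recode(df$metric, kl = "KL(real || synth)",
                             ks_p = "KS p-value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(
      data = data.frame(metric = "KS p-value", y = 0.05),
      ggplot2::aes(yintercept = .data$y), linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Synthetic-cohort fidelity by parameter")
}

#' Plot profiles in standardized space coloured by archetype
#'
#' @param profiles Data frame of profile columns.
#' @param model A fitted `cluster_model`.
#' @param dims Two profile columns to display.
#' @return A ggplot object.
#' @export
plot_profile_clusters <- function(profiles, model,
                                  dims = c("s_rmssd", "s_pnn50")) {
  asg <- assign_cluster(profiles, model)
  df <- dplyr::bind_cols(tibble::as_tibble(profiles)[dims], asg)
  cent <- tidy(model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[dims[1]]], y = .data[[dims[2]]],
                                   colour = .data$archetype)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(title = "HRV profile archetypes", colour = NULL) +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot a toy-training trace
#'
#' Loss components, expert-utilization CV and activation entropy per epoch.
#'
#' @param result Output of [toy_train()].
#' @return A ggplot object.
#' @export
plot_training_trace <- function(result) {
  df <- tidyr::pivot_longer(result$trace, -"epoch",
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(title = "Profile-aided MoE toy training")
}
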