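PSA_PANEL_LABELS <- c(
  exacerbations = "Total exacerbations over horizon",
  cost_total = "Total discounted costs (GBP 2022)",
  life_years = "Total life years",
  qalys = "Total discounted QALYs"
)

# one mean-with-interval panel per outcome, mirroring the standard
# adherence-vs-outcome summary figure layout
plot_psa_panel <- function(summary_df, outcome, file) {
  s <- summary_df[summary_df$outcome == outcome, ]
  png(file, width = 900, height = 650, res = 120)
  on.exit(dev.off())
  par(mar = c(4.5, 4.8, 2.5, 1))
  ylim <- range(s$lower, s$upper)
  plot(100 * s$adherence, s$mean, type = "n", ylim = ylim,
       xlab = "Medication adherence (%)", ylab = PSA_PANEL_LABELS[[outcome]],
       main = PSA_PANEL_LABELS[[outcome]])
  nz <- s$upper > s$lower   # zero-width intervals (all-fixed tags) have no bar
  if (any(nz))
    arrows(100 * s$adherence[nz], s$lower[nz], 100 * s$adherence[nz], s$upper[nz],
           angle = 90, code = 3, length = 0.04, col = "grey40")
  lines(100 * s$adherence, s$mean, col = "steelblue4", lwd = 2)
  points(100 * s$adherence, s$mean, pch = 19, col = "steelblue4")
  mtext("mean with 95% percentile interval", side = 3, cex = 0.7, line = 0.2)
  invisible(file)
}

#' Write the four adherence-vs-outcome PSA panels
#'
#' One PNG per headline outcome (exacerbations, discounted costs, life
#' years, discounted QALYs against the adherence grid), each showing the
#' Monte-Carlo mean and 95% percentile interval. Tables remain the
#' canonical artifact; the plots are a convenience layer.
#'
#' @param r A `psa_result`.
#' @param dir Output directory.
#' @return Character vector of the files written, invisibly.
#' @export
plot_psa <- function(r, dir = ".") {
  files <- character(0)
  for (oc in names(PSA_PANEL_LABELS)) {
    f <- file.path(dir, sprintf("psa_%s.png", oc))
    plot_psa_panel(r$summary, oc, f)
    files <- c(files, f)
  }
  invisible(files)
}
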