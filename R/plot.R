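#' Difference-versus-duration curves
#'
#' Simple line chart of predicted outcome differences against reallocated
#' minutes, one curve per donor behaviour, for a fixed receiving behaviour
#' (or vice versa). Base graphics; intended as a quick look at a
#' [difference_grid()].
#'
#' @param grid A data frame from [difference_grid()].
#' @param fix `"to"` (default) to fix the receiving part, `"from"` to fix
#'   the donor.
#' @param part The fixed part; default the model's last part (conventionally
#'   mvpa).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the wide matrix of plotted differences.
#' @export
plot_difference_curves <- function(grid, fix = c("to", "from"), part = NULL, ...) {
  fix <- match.arg(fix)
  other <- if (fix == "to") "from" else "to"
  if (is.null(part)) part <- utils::tail(sort(unique(grid$to)), 1)
  sub <- grid[grid[[fix]] == part & grid$feasible, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no feasible rows for ", fix, " = ", part)
  durations <- sort(unique(sub$minutes))
  counterparts <- sort(unique(sub[[other]]))
  m <- sapply(counterparts, function(p) {
    s <- sub[sub[[other]] == p, ]
    s$difference[match(durations, s$minutes)]
  })
  graphics::matplot(durations, m, type = "l", lty = 1, lwd = 2,
                    xlab = "reallocated minutes",
                    ylab = paste("predicted difference in", sub$outcome[1]),
                    main = sprintf("%s %s", if (fix == "to") "time moved into" else "time moved out of", part),
                    ...)
  graphics::abline(h = 0, col = "grey70", lty = 2)
  graphics::legend("topleft", legend = counterparts, col = seq_along(counterparts),
                   lty = 1, lwd = 2, bty = "n",
                   title = if (fix == "to") "from" else "to")
  invisible(m)
}
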