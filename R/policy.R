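#' Flexible-staffing policy
#'
#' Defines how shortfalls are covered after the baseline establishment is
#' set: whether within-division redeployment runs, and the probability that
#' a short-notice bank or agency request for one block is fulfilled, by
#' staff group and period. Four named modes mirror the scenario grid:
#'
#' * `none` — no redeployment, no temporary staff.
#' * `empirical` — availability in the 5\%-45\% range reported for
#'   short-notice requests, higher for assistants and in the daytime.
#' * `higher` — all probabilities 0.75.
#' * `unlimited` — all probabilities 1.
#'
#' Productivity factors discount the achieved (effective) hours of
#' non-permanent staff: redeployed and bank staff work at 90\% efficiency,
#' agency staff at 75\%.
#'
#' @param mode policy mode name.
#' @param availability optional override: list with elements `bank` and
#'   `agency`, each a `2 x 4` matrix (rows `rn`, `hca`; columns periods
#'   0..3) of fulfilment probabilities in `[0, 1]`.
#' @param productivity named efficiency factors
#'   `c(redeploy = 0.9, bank = 0.9, agency = 0.75)`.
#' @return list of class `flex_policy`.
#' @export
flex_policy <- function(mode = c("empirical", "none", "higher", "unlimited"),
                        availability = NULL,
                        productivity = c(redeploy = 0.9, bank = 0.9,
                                         agency = 0.75)) {
  mode <- match.arg(mode)
  if (is.null(availability)) availability <- default_availability(mode)
  for (ch in c("bank", "agency")) {
    a <- availability[[ch]]
    if (!is.matrix(a) || !identical(dim(a), c(2L, 4L)) ||
        any(a < 0 | a > 1))
      stop("flex_policy: availability$", ch,
           " must be a 2 x 4 probability matrix")
  }
  if (any(productivity < 0 | productivity > 1))
    stop("flex_policy: productivity factors must lie in [0, 1]")
  structure(list(mode = mode,
                 availability = availability,
                 productivity = productivity[c("redeploy", "bank", "agency")],
                 redeployment_enabled = mode != "none"),
            class = "flex_policy")
}

# Default availability tables by mode. The empirical table is synthetic but
# spans the reported 5%-45% short-notice fulfilment range: morning/afternoon
# ("day") highest, night lowest; assistants easier to find than registered
# nurses; agency 10 points below bank, floored at 5%.
default_availability <- function(mode) {
  av <- function(p) matrix(p, nrow = 2, byrow = TRUE,
                           dimnames = list(c("rn", "hca"), NULL))
  switch(mode,
         none = list(bank = av(rep(0, 8)), agency = av(rep(0, 8))),
         unlimited = list(bank = av(rep(1, 8)), agency = av(rep(1, 8))),
         higher = list(bank = av(rep(0.75, 8)), agency = av(rep(0.75, 8))),
         empirical = {
           bank <- av(c(0.35, 0.35, 0.25, 0.15,    # rn: day, day, eve, night
                        0.45, 0.45, 0.35, 0.25))   # hca
           list(bank = bank, agency = pmax(bank - 0.10, 0.05))
         })
}
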