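#' Flux balance analysis
#'
#' Maximizes (by default) the biomass flux subject to the steady-state and
#' bound constraints.
#'
#' @param net a \code{\link{MetabolicNetwork}}.
#' @param objective reaction id to optimize (default biomass).
#' @param maximize logical.
#' @return list with \code{status}, \code{objval} and named flux vector
#'   \code{fluxes}.
#' @export
fba <- function(net, objective = biomassId(net), maximize = TRUE) {
  S <- stoichiometry(net)
  n <- ncol(S)
  obj <- numeric(n); obj[match(objective, reactionIds(net))] <- 1
  res <- solveLp(obj, S, rep("==", nrow(S)), rep(0, nrow(S)),
                 lowerBounds(net), upperBounds(net), maximize = maximize)
  fluxes <- res$x; names(fluxes) <- reactionIds(net)
  list(status = res$status, objval = res$objval, fluxes = fluxes)
}

#' Flux variability analysis
#'
#' Per-reaction LP minimum and maximum of flux subject to steady state,
#' bounds, and a biomass growth floor.
#'
#' @param net a \code{\link{MetabolicNetwork}}.
#' @param reactions reaction ids or indices (default all).
#' @param growthFloor minimum biomass flux (1/h); 0 disables the floor.
#' @return data.frame (reaction, min, max).
#' @export
fluxVariability <- function(net, reactions = reactionIds(net),
                            growthFloor = 0) {
  S <- stoichiometry(net)
  n <- ncol(S)
  if (is.numeric(reactions)) reactions <- reactionIds(net)[reactions]
  jx <- match(reactions, reactionIds(net))
  if (anyNA(jx)) stop("unknown reactions")
  lb <- lowerBounds(net); ub <- upperBounds(net)
  bio <- match(biomassId(net), reactionIds(net))
  lb[bio] <- max(lb[bio], growthFloor)
  if (lb[bio] > ub[bio]) stop("infeasible model: growth floor above biomass upper bound")
  ## feasibility check first so infeasibility is reported distinctly
  feas <- solveLp(numeric(n), S, rep("==", nrow(S)), rep(0, nrow(S)), lb, ub)
  if (feas$status == "infeasible")
    stop("infeasible model under the requested growth floor")
  if (feas$status != "optimal") stop("solver failure: ", feas$status)
  mins <- maxs <- numeric(length(jx))
  for (k in seq_along(jx)) {
    obj <- numeric(n); obj[jx[k]] <- 1
    lo <- solveLp(obj, S, rep("==", nrow(S)), rep(0, nrow(S)), lb, ub)
    hi <- solveLp(obj, S, rep("==", nrow(S)), rep(0, nrow(S)), lb, ub,
                  maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("solver failure on reaction ", reactions[k])
    mins[k] <- lo$objval; maxs[k] <- hi$objval
  }
  data.frame(reaction = reactions, min = mins, max = maxs,
             stringsAsFactors = FALSE)
}
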