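#' Maximum burnable fraction of a cell
#'
#' The fire return interval (FRI) and time since last fire (tsf) limit the
#' portion of a grid cell that can burn: the longer a cell goes without
#' fire, the larger the fraction available, linearly up to the whole cell
#' at `tsf = fri`.
#'
#' @param tsf years since last fire, `>= 0`. Vectorized.
#' @param fri fire return interval in years, `>= 1`.
#' @return burn fraction `min(1, tsf / fri)`.
#' @export
#' @examples
#' max_burn_fraction(c(0, 75, 200), 150)
max_burn_fraction <- function(tsf, fri) {
  if (any(fri <= 0)) stop("configuration error: fri must be positive")
  if (any(tsf < 0)) stop("tsf must be nonnegative")
  pmin(1, tsf / fri)
}

#' Default fire consumption/mortality fractions
#'
#' Maximum fractions (at full burn, severity one) of each aboveground pool
#' consumed or killed by fire; severity and burned fraction scale them
#' linearly. Soil carbon and live roots are untouched.
#'
#' @return named list: `leaf`, `litter`, `standing_dead` (consumed
#'   fractions), `wood_kill` (live wood killed), `wood_kill_consumed`
#'   (fraction of the killed wood consumed; the rest transfers to standing
#'   dead).
#' @export
default_consumption <- function() {
  list(leaf = 0.9, litter = 0.7, standing_dead = 0.5,
       wood_kill = 0.15, wood_kill_consumed = 0.1)
}

#' Create a set of carbon pools
#'
#' @param leaf_c,live_wood_above_c,live_root_c live pools, g C m-2.
#' @param standing_dead_c,litter_c,soil_c dead pools, g C m-2.
#' @return list of class `vf_pools` of six nonnegative, equal-length
#'   numeric vectors.
#' @export
carbon_pools <- function(leaf_c = 0, live_wood_above_c = 0, live_root_c = 0,
                         standing_dead_c = 0, litter_c = 0, soil_c = 0) {
  p <- list(leaf_c = leaf_c, live_wood_above_c = live_wood_above_c,
            live_root_c = live_root_c, standing_dead_c = standing_dead_c,
            litter_c = litter_c, soil_c = soil_c)
  n <- max(lengths(p))
  p <- lapply(p, rep, length.out = n)
  if (any(unlist(p) < 0)) stop("invariant violation: negative carbon pool")
  structure(p, class = "vf_pools")
}

#' Total, live, and dead carbon of a pool set
#'
#' @param pools a [carbon_pools()] list.
#' @return for `live_c`/`dead_c`/`ecosystem_c`: numeric vectors, g C m-2.
#' @export
live_c <- function(pools) {
  pools$leaf_c + pools$live_wood_above_c + pools$live_root_c
}

#' @rdname live_c
#' @export
dead_c <- function(pools) {
  pools$standing_dead_c + pools$litter_c + pools$soil_c
}

#' @rdname live_c
#' @export
ecosystem_c <- function(pools) live_c(pools) + dead_c(pools)

#' Apply fire consumption and mortality to carbon pools
#'
#' Consumes fractions of the aboveground pools (leaf, litter, standing
#' dead) over the burned fraction of the cell, kills a fraction of live
#' wood (a share of which is consumed, the rest transferred to standing
#' dead), and leaves soil carbon and roots untouched. Total carbon is
#' conserved: the sum of the returned pools plus `consumed_c` equals the
#' input sum exactly.
#'
#' @param pools a [carbon_pools()] list (vectors over cells).
#' @param frac_burned fraction of cell area burned, in `[0, 1]`.
#' @param severity fuel-dryness scalar in `[0, 1]`, linearly scaling the
#'   consumption fractions.
#' @param consumption a [default_consumption()] list.
#' @return list with `pools` (updated) and `event`: `consumed_c` (g C m-2
#'   emitted) and `killed_c` (g C m-2 moved live to dead).
#' @export
consume_and_kill <- function(pools, frac_burned, severity = 1,
                             consumption = default_consumption()) {
  if (any(unlist(pools) < 0)) stop("invariant violation: negative carbon pool")
  if (any(frac_burned < 0 | frac_burned > 1))
    stop("frac_burned must be in [0, 1]")
  eff <- frac_burned * pmin(pmax(severity, 0), 1)
  burn_leaf <- pools$leaf_c * eff * consumption$leaf
  burn_litter <- pools$litter_c * eff * consumption$litter
  burn_sd <- pools$standing_dead_c * eff * consumption$standing_dead
  killed <- pools$live_wood_above_c * eff * consumption$wood_kill
  killed_burn <- killed * consumption$wood_kill_consumed
  pools$leaf_c <- pools$leaf_c - burn_leaf
  pools$litter_c <- pools$litter_c - burn_litter
  pools$standing_dead_c <- pools$standing_dead_c - burn_sd +
    (killed - killed_burn)
  pools$live_wood_above_c <- pools$live_wood_above_c - killed
  consumed <- burn_leaf + burn_litter + burn_sd + killed_burn
  list(pools = pools,
       event = list(consumed_c = consumed, killed_c = killed))
}
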