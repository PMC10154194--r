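## Residual streams: by-product generation through technical conversion
## factors, the split of consumption waste between animal feed and compost,
## sewage-sludge fertilizer value and compost nutrient pass-through.

#' By-products of a processing step
#'
#' Technical conversion factors give the fraction of main product and of
#' each by-product obtained from a unit of raw input (e.g. flour and bran
#' from wheat milling). Mass out never exceeds mass in.
#'
#' @param input_t raw input, t
#' @param tcf named numeric vector of output fractions (must sum to <= 1)
#' @return named numeric vector of output masses, t
#' @export
byproducts_from_processing <- function(input_t, tcf) {
  if (sum(tcf) > 1 + 1e-9)
    stop_cf("technical conversion factors sum to %.4f > 1", sum(tcf))
  if (input_t < 0) stop_cf("input mass must be >= 0")
  input_t * tcf
}

#' Split consumption waste into feed-eligible and compostable shares
#'
#' A fixed share of consumption waste (default 35%) is available to
#' animals as a wet feed, restricted to monogastric animals and fish and
#' to the country where the waste arises; the remainder is available for
#' composting.
#'
#' @param waste_t consumption waste, t
#' @param params the instance `residual_params` list
#' @return list with `feed_eligible_t` and `compostable_t`
#' @export
waste_feed_allocation <- function(waste_t, params) {
  if (waste_t < 0) stop_cf("waste mass must be >= 0")
  f <- params$waste_to_feed_frac
  list(feed_eligible_t = f * waste_t, compostable_t = (1 - f) * waste_t)
}

#' Fertilizer value of sewage sludge
#'
#' Only a fixed share of sludge (default 36%) is used in agriculture; the
#' usable mass carries 7.5% N and 1.2% P by default.
#'
#' @param sludge_fresh_t sludge produced, t fresh matter
#' @param params the instance `residual_params` list
#' @param already_usable set TRUE when `sludge_fresh_t` is the applied
#'   (post-use-share) quantity rather than the produced one
#' @return list with `usable_t`, `n_t`, `p_t`
#' @export
sludge_fertilizer <- function(sludge_fresh_t, params, already_usable = FALSE) {
  if (sludge_fresh_t < 0) stop_cf("sludge mass must be >= 0")
  usable <- if (already_usable) sludge_fresh_t
            else params$sludge_use_frac * sludge_fresh_t
  list(usable_t = usable,
       n_t = usable * params$sludge_n_frac,
       p_t = usable * params$sludge_p_frac)
}

#' Nutrients reaching the soil from composted waste
#'
#' N and P in the composted material pass through to the soil, except for
#' the gaseous N share lost during composting; P is conserved exactly.
#'
#' @param n_in_t,p_in_t nutrients entering the composter, t
#' @param n_gaseous_loss_frac fraction of N lost as gas (from the instance
#'   residual parameters)
#' @return list with `n_t` and `p_t` delivered to soil
#' @export
compost_nutrients <- function(n_in_t, p_in_t, n_gaseous_loss_frac) {
  if (n_in_t < 0 || p_in_t < 0) stop_cf("compost nutrient inputs must be >= 0")
  list(n_t = n_in_t * (1 - n_gaseous_loss_frac), p_t = p_in_t)
}
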