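#' Unit conversions for carbon accounting
#'
#' The accounting chain runs in three unit systems: per-horizon carbon density
#' in g m-2, per-site density in tC ha-1, and population stocks in PgC.
#' Conversions: 1 g m-2 = 0.01 tC ha-1 (10,000 m2 ha-1 / 1e6 g t-1), and
#' 1 tC ha-1 over 1e6 ha = 1e-3 PgC (1e15 g Pg-1).
#'
#' @param x numeric vector, g m-2.
#' @return `g_m2_to_tC_ha`: density in tC ha-1.
#' @examples
#' g_m2_to_tC_ha(5000)           # 50 tC ha-1
#' stock_PgC(400, area_ha = 1e6) # 0.4 PgC
#' @export
g_m2_to_tC_ha <- function(x) x / 100

#' @rdname g_m2_to_tC_ha
#' @param density_tC_ha density in tC ha-1.
#' @param area_ha area in hectares.
#' @return `stock_PgC`: total stock in PgC (t -> g -> Pg: x 1e6 / 1e15).
#' @export
stock_PgC <- function(density_tC_ha, area_ha) density_tC_ha * area_ha * 1e6 / 1e15

# area term of the horizon carbon density equation, cm2 m-2
A_CM2_PER_M2 <- 10000
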