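# Builds the synthetic optical fixtures shipped under inst/extdata/.
#
# The hemoglobin extinction curves are smooth spline interpolants through a
# coarse anchor table of literature-magnitude values (Zijlstra/Prahl-style
# compilations), converted from decadic molar extinction (cm^-1 M^-1) to
# natural-log extinction in mm^-1 uM^-1.  They reproduce the qualitative
# features the band design relies on (green isosbestic region, steep oxy/deoxy
# separation around 600-650 nm, near-infrared crossover around 800 nm) but are
# NOT measured data: filenames and headers flag them as synthetic.
#
# Run from the package root:  Rscript data-raw/spectra_synthetic.R

to_natural_per_mm_per_uM <- function(decadic_cm_M) decadic_cm_M * 1e-7 * log(10)

anchors <- data.frame(
  wl  = c(450, 475, 500, 515, 530, 542, 555, 560, 570, 577, 585, 595,
          610, 626, 650, 680, 700, 730, 760, 785, 800, 850, 900, 950, 1000),
  hbo = c(62800, 30000, 20900, 21500, 39000, 53200, 42000, 32000, 39000,
          50000, 30000, 10000, 1800, 740, 370, 320, 290, 390, 590, 740,
          815, 1060, 1200, 1210, 1100),
  hbr = c(90000, 42000, 22000, 21000, 30000, 41000, 50000, 51000, 45000,
          38000, 30000, 18000, 9000, 5100, 3750, 2400, 1800, 1300, 1670,
          1100, 880, 690, 750, 650, 500)
)

grid <- seq(450, 1000, by = 2)
interp_log <- function(wl, val) {
  exp(stats::spline(wl, log(val), xout = grid, method = "natural")$y)
}

write_curve <- function(path, wl, value, kind, units) {
  con <- file(path, "w")
  writeLines(sprintf("# kind: %s", kind), con)
  writeLines(sprintf("# units: %s", units), con)
  writeLines("# provenance: synthetic fixture (see data-raw/spectra_synthetic.R)", con)
  write.csv(data.frame(wavelength_nm = wl, value = signif(value, 6)),
            con, row.names = FALSE, quote = FALSE)
  close(con)
}

out <- "inst/extdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

write_curve(file.path(out, "extinction_hbo_synthetic.csv"), grid,
            to_natural_per_mm_per_uM(interp_log(anchors$wl, anchors$hbo)),
            "extinction", "mm^-1.uM^-1 (natural log)")
write_curve(file.path(out, "extinction_hbr_synthetic.csv"), grid,
            to_natural_per_mm_per_uM(interp_log(anchors$wl, anchors$hbr)),
            "extinction", "mm^-1.uM^-1 (natural log)")

# Reduced scattering: smooth power-law decay of cortical-tissue magnitude.
write_curve(file.path(out, "musp_synthetic.csv"), grid,
            2.2 * (grid / 500)^(-1.1),
            "mu_s_prime", "mm^-1")

# LED emission spectra: Gaussian lines at the nominal diode wavelengths.
led <- function(center, sd) {
  wl <- seq(center - 45, center + 45, by = 1)
  list(wl = wl, val = exp(-0.5 * ((wl - center) / sd)^2))
}
g <- led(525, 13); r <- led(626, 8); i <- led(850, 15)
write_curve(file.path(out, "led_green_525_synthetic.csv"), g$wl, g$val,
            "emission", "arbitrary")
write_curve(file.path(out, "led_red_626_synthetic.csv"), r$wl, r$val,
            "emission", "arbitrary")
write_curve(file.path(out, "led_ir_850_synthetic.csv"), i$wl, i$val,
            "emission", "arbitrary")
cat("wrote fixtures to", out, "\n")
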