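# Builds inst/extdata/chromophores.csv: per-wavelength absorption
# coefficients for the default neonatal skin model. These are smooth
# in-package defaults with the qualitative shape of the standard
# chromophore spectra (melanin power-law decay, hemoglobin Soret and
# Q bands, bilirubin band near 460 nm); they are documented fixture
# constants, user-overridable, not measured values.
#
# Units: 1/mm, except mua_bilirubin_per_mgdl which is 1/mm per mg/dL
# of the dermal bilirubin proxy concentration.

wl <- seq(395, 705, by = 5)

# interior-melanosome absorption, power-law decay with wavelength
mua_melanosome <- 6.6e9 * wl^-3.33

# whole-blood absorption, oxygenated: Soret band ~415 nm, Q bands 542/577 nm
mua_blood_oxy <- 65 * exp(-0.5 * ((wl - 415) / 20)^2) +
  3.0 * exp(-0.5 * ((wl - 542) / 12)^2) +
  3.2 * exp(-0.5 * ((wl - 577) / 10)^2) +
  0.10 * exp(-0.5 * ((wl - 650) / 60)^2) + 0.05

# whole-blood absorption, deoxygenated: Soret ~432 nm, single Q band ~556 nm,
# heavier red tail than oxygenated blood
mua_blood_deoxy <- 55 * exp(-0.5 * ((wl - 432) / 22)^2) +
  3.5 * exp(-0.5 * ((wl - 556) / 18)^2) +
  0.35 * exp(-0.5 * ((wl - 640) / 80)^2) + 0.08

# dermal bilirubin proxy: single band centred at 460 nm, effectively zero
# above ~560 nm so the red channel is insensitive to bilirubin
mua_bilirubin_per_mgdl <- 0.0075 * exp(-0.5 * ((wl - 460) / 33)^2)

# flat bloodless/pigmentless tissue baseline
mua_baseline <- rep(0.015, length(wl))

tab <- data.frame(
  wavelength_nm = wl,
  mua_melanosome = signif(mua_melanosome, 6),
  mua_blood_oxy = signif(mua_blood_oxy, 6),
  mua_blood_deoxy = signif(mua_blood_deoxy, 6),
  mua_bilirubin_per_mgdl = signif(mua_bilirubin_per_mgdl, 6),
  mua_baseline = mua_baseline
)

write.csv(tab, file.path("inst", "extdata", "chromophores.csv"),
          row.names = FALSE, quote = FALSE)
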