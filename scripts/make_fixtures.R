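# Regenerates inst/extdata/mit_strategies_synthetic.csv, the packaged
# synthetic MIT strategy fixture: 27 strategies (3 DR categories x 3 soils x
# 3 regions), one row per strategy-year. The fixture is data, not code, so
# real strategy tables can replace it without code changes. Run from the
# repository root: Rscript scripts/make_fixtures.R

yr <- function(crop, sow, till, stale, gapp, gdose, sapp, sdose, rate) {
  data.frame(crop = crop, sowing_window = sow, tillage = till,
             n_stale_seedbeds = stale, glyphosate_applications = gapp,
             glyphosate_dose = gdose, selective_applications = sapp,
             selective_dose = sdose, seed_rate = rate,
             stringsAsFactors = FALSE)
}

# Rotation templates. Constraints encoded (relative to BAU: 4 wheat years,
# 4 stale seedbeds, glyphosate 6 l/ha, selective 10 l/ha):
#  - every strategy has >= 1 spring crop and > 4 stale seedbeds;
#  - LD-LR: total herbicide < 16 l/ha, 4 wheat years, reduced applications;
#  - LD-HR: 3 wheat years, glyphosate ~2x BAU, selective slightly reduced;
#  - HD-HR: 2 wheat years, glyphosate = 3x BAU (18 l/ha), heavy selective
#    on wheat, up to four stale seedbeds in spring years; eastern rotation
#    carries 4 spring crops.
template <- function(dr, region, till_wheat, till_spring, rate) {
  # LD-LR leans on non-chemical control: two stale seedbeds per wheat year,
  # reduced herbicide programme
  w_ldlr <- yr("winter_wheat", "late_autumn", till_wheat, 2, 1, 1.0, 1, 1.5, rate)
  w_ldhr <- yr("winter_wheat", "late_autumn", till_wheat, 1, 1, 1.5, 2, 2.0, rate)
  w_hdhr <- yr("winter_wheat", "late_autumn", till_wheat, 1, 2, 2.25, 2, 3.0, rate)
  osr    <- yr("winter_oilseed_rape", "early_autumn", till_wheat, 0, 0, 0, 1, 1.0, 1.0)
  if (dr == "LD-LR") {
    sp <- yr(if (region == "east") "spring_beans" else "spring_barley",
             "spring", till_spring, 2, 1, 1.5, 1, 0.5, rate)
    if (region == "east") {
      rbind(w_ldlr, w_ldlr, osr, w_ldlr, w_ldlr, sp)
    } else {
      rbind(w_ldlr, sp, w_ldlr, osr, w_ldlr, w_ldlr)
    }
  } else if (dr == "LD-HR") {
    sp1 <- yr("spring_beans", "spring", till_spring, 2, 2, 3.75, 1, 1.25, rate)
    sp2 <- yr("spring_barley", "spring", till_spring, 2, 2, 3.75, 1, 1.25, rate)
    rbind(w_ldhr, sp1, w_ldhr, sp2, osr, w_ldhr)
  } else {
    if (region == "east") {
      sp <- function(crop) yr(crop, "spring", till_spring, 3, 3, 3.375, 1, 0.5, rate)
      rbind(sp("spring_barley"), sp("spring_beans"), w_hdhr,
            sp("spring_oats"), sp("spring_barley"), w_hdhr)
    } else {
      sp <- function(crop, stale) yr(crop, "spring", till_spring, stale, 3, 4.5, 1, 0.5, rate)
      rbind(sp("spring_barley", 4), w_hdhr, sp("spring_oats", 3),
            sp("spring_beans", 3), w_hdhr, osr)
    }
  }
}

rows <- list()
for (dr in c("LD-LR", "LD-HR", "HD-HR")) {
  for (soil in c("heavy", "medium", "light")) {
    for (region in c("north", "central", "east")) {
      till_wheat <- if (soil == "light" && dr != "LD-LR") "no_till"
        else "min_till"
      till_spring <- if (soil == "heavy" && dr == "LD-HR")
        "inversion_plough" else "min_till"
      rate <- if (dr == "HD-HR") 1.3 else 1.2
      t6 <- template(dr, region, till_wheat, till_spring, rate)
      id <- paste("MIT", dr, soil, region, sep = "_")
      rows[[id]] <- cbind(strategy_id = id, scenario = "MIT",
                          dr_category = dr, soil = soil, region = region,
                          year = 1:6, t6)
    }
  }
}
out <- do.call(rbind, rows)
rownames(out) <- NULL
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write.csv(out, "inst/extdata/mit_strategies_synthetic.csv",
          row.names = FALSE)
cat("wrote", nrow(out), "rows\n")
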