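## Nuclear-geometry statistics: radial FISH distances normalized by the
## sphere-equivalent nuclear radius, compared between conditions by a
## Mann-Whitney U test; diameter intensity profiles aligned on the
## envelope-marker peaks, averaged, and compared in the 0-0.15R
## peripheral zone.
source("analysis/00_common.R")

message("== 06: nuclear geometry ==")
nuclei <- utils::read.delim(file.path(RAW, "nuclei.tsv"))
by_cond <- split(nuclei, nuclei$condition)

## recompute normalized distances from raw distance + volume, as the
## measurement pipeline would
nd <- lapply(by_cond, function(df)
  as.numeric(suppressWarnings(
    normalized_radial_distance(df$distance, df$volume))))
cmp <- compare_distance_distributions(nd$control, nd$kd)
message(sprintf(
  "radial distance: control median %.3fR vs kd %.3fR (M-W U p = %.3g)",
  cmp$median_a, cmp$median_b, cmp$p_value))
write_tsv(data.frame(condition = rep(names(nd), lengths(nd)),
                     norm_distance = unlist(nd)),
          file.path(RES, "normalized_distances.tsv"))

prof_tab <- utils::read.delim(file.path(RAW, "diameter_profiles.tsv"))
to_list <- function(df) lapply(split(df, df$nucleus), function(p)
  list(signal = p$signal[order(p$position)],
       ne = p$ne[order(p$position)]))
profs <- lapply(split(prof_tab, prof_tab$condition), to_list)

avg_ctrl <- align_and_average_profiles(profs$control)
avg_kd <- align_and_average_profiles(profs$kd)
write_tsv(avg_ctrl, file.path(RES, "profile_diameter_ctrl.tsv"))
write_tsv(avg_kd, file.path(RES, "profile_diameter_kd.tsv"))

zt <- peripheral_zone_test(profs$control, profs$kd, zone = cfg$zone)
message(sprintf(
  "peripheral 0-%.2fR zone: control mean %.3f vs kd %.3f (p = %.3g)",
  cfg$zone, zt$mean_a, zt$mean_b, zt$p_value))
write_tsv(data.frame(zone = cfg$zone, mean_control = zt$mean_a,
                     mean_kd = zt$mean_b, n_control = zt$n_a,
                     n_kd = zt$n_b, p_value = zt$p_value),
          file.path(RES, "peripheral_zone_test.tsv"))
message("analysis chain complete; tables under ", RES)
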