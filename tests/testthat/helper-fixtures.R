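# Shared fixtures, memoized so expensive enumerations run once per
# test session.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(key, builder) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- builder()
  .fx_cache[[key]]
}

fx_registry <- function() fx("registry", default_registry)

fx_lead_11_10_8 <- function() {
  fx("lead", function() {
    reg <- fx_registry()
    acylate(open_epoxide(get_block(reg, "amine-11"),
                         get_block(reg, "epoxide-10"), 2),
            get_block(reg, "acyl-8"), 2)
  })
}

fx_screen_libraries <- function() {
  fx("screen12", function() {
    reg <- fx_registry()
    screen_library(reg, list(library1_design(reg), library2_design(reg)))
  })
}

fx_screen_factorial <- function() {
  fx("screen_full", function() {
    reg <- fx_registry()
    screen_library(reg, full_factorial_design(reg))
  })
}

# Write a registry CSV from a data.frame-like list of rows.
write_registry_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  df <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

bb_row <- function(id, kind, structure, carbon_count, label = "",
                   salt_form = FALSE) {
  data.frame(id = id, kind = kind, structure = structure,
             carbon_count = carbon_count, label = label,
             salt_form = salt_form, stringsAsFactors = FALSE)
}
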