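#' Build the scenario set for a care type
#'
#' Scenario 1 (the technical baseline) uses inputs places, staff FTE per
#' user and budget per place, and outputs length of stay, occupancy (%) and
#' movers per place. Each further scenario adds exactly one size-scaled
#' quality domain as an extra output, in the fixed study order: living
#' environment, therapeutic environment, self-management and autonomy,
#' social interface, human rights, treatments and interventions,
#' recovery-based practice. Residential care and supported housing get 8
#' scenarios; floating outreach, which lacks the living-environment domain,
#' gets 7.
#'
#' @param care_type one of [care_types()].
#' @return a list of objects of class `"scenario"`, each with `id`,
#'   `label`, `inputs`, `outputs`, `quality_domain` (`NA` for the
#'   baseline) and `care_type`.
#' @export
build_scenarios <- function(care_type) {
  care_type <- match.arg(care_type, care_types())
  base_inputs <- c("places", "staff_per_user", "budget_per_place")
  base_outputs <- c("length_of_stay", "occupancy_pct", "movers_per_place")
  domain_order <- c("living_environment", "therapeutic_environment",
                    "self_management_autonomy", "social_interface",
                    "human_rights", "treatments_interventions",
                    "recovery_practice")
  domain_order <- intersect(domain_order, quirc_domains(care_type))

  mk <- function(id, label, quality_domain = NA_character_) {
    outs <- base_outputs
    if (!is.na(quality_domain)) outs <- c(outs, paste0("qs_", quality_domain))
    structure(list(id = id, label = label, inputs = base_inputs,
                   outputs = outs, quality_domain = quality_domain,
                   care_type = care_type),
              class = "scenario")
  }
  scenarios <- c(
    list(mk(1L, "Baseline (technical variables only)")),
    lapply(seq_along(domain_order), function(k)
      mk(k + 1L, paste("Baseline +", gsub("_", " ", domain_order[k])),
         domain_order[k]))
  )
  names(scenarios) <- paste0("scenario_", vapply(scenarios, `[[`, integer(1), "id"))
  scenarios
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario %d (%s): %s\n  inputs : %s\n  outputs: %s\n",
              x$id, x$care_type, x$label,
              paste(x$inputs, collapse = ", "),
              paste(x$outputs, collapse = ", ")))
  invisible(x)
}
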