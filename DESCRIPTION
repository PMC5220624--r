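Package: cprplr
Title: Lumped-Parameter Hemodynamics of Chest-Compression CPR with
    Passive Leg Raising
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-loop, fourteen-compartment lumped-parameter model of the
    human circulation during chest-compression-only cardiopulmonary
    resuscitation (CO-CPR), with an optional passive leg raising (PLR)
    maneuver. Chest compressions drive the circulation through intrathoracic
    and mediastinal pressure sources whose reach over the chest compartments
    is controlled by a thoracic pump factor (0 = pure cardiac pump, 1 = pure
    thoracic pump); leg raising adds a gravitational hydrostatic pressure to
    the femoral compartments. The volume state is integrated with a
    fixed-step fourth-order Runge-Kutta scheme over diode-valve RC network
    dynamics. Utilities reduce simulated traces to cardiac output, coronary
    perfusion pressure, regional flows and volumes over steady-state
    windows, compare hemodynamics before and after leg raising, sweep the
    thoracic pump factor and the leg elevation angle, and screen peripheral
    pulmonary venous pressure against the colloid-osmotic oedema threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
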