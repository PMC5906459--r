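Package: plateflow
Title: Serial Fluid Delivery from Multiwell Plates to Microfluidic Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Software model of a robotic system that serially delivers fluids
    from multiwell plates to a microfluidic device through a single inlet
    tube. Provides plate geometry and traversal orders, the serial command
    codec for plate and tube positioning, a protocol compiler producing timed
    valve, servo, plate, stimulus and acquisition event streams, a fluidic
    digital twin (Taylor-Aris breakthrough during a fluid switch, well-to-well
    carryover with washes, backpressure balance classification), synthetic
    fluorescence data generators, and quantification pipelines for carryover
    percentage, GCaMP dF/F0 dose-response with Hill/EC50 fitting, a paired
    solvent screen with Bonferroni correction, and staining time-course
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
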