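# Default PHI tag list: DICOM tag keywords stripped by anonymization and
# excluded from plug-in metadata. One keyword per line. Private tags (odd
# group numbers) are always stripped in addition to this list.
PatientName
PatientID
PatientBirthDate
PatientSex
PatientAddress
ReferringPhysicianName
InstitutionName
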