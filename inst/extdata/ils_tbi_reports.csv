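"report_date","treatment_type","category","classification","planning_related"
2013-02-10,"TBI","treatment","operational_workflow",FALSE
2013-05-11,"TBI","treatment","operational_workflow",FALSE
2013-08-10,"TBI","treatment","operational_workflow",FALSE
2013-11-10,"TBI","treatment","operational_workflow",FALSE
2014-02-10,"TBI","treatment","operational_workflow",FALSE
2014-05-11,"TBI","treatment","operational_workflow",FALSE
2014-08-10,"TBI","treatment","unsafe_condition",FALSE
2014-11-10,"TBI","treatment","unsafe_condition",FALSE
2015-02-10,"TBI","treatment","unsafe_condition",FALSE
2015-05-11,"TBI","treatment","near_miss",FALSE
2015-08-10,"TBI","treatment","near_miss",FALSE
2015-11-10,"TBI","documentation","operational_workflow",TRUE
2016-02-10,"TBI","documentation","operational_workflow",TRUE
2016-05-11,"TBI","documentation","operational_workflow",TRUE
2016-08-10,"TBI","documentation","operational_workflow",TRUE
2016-11-10,"TBI","documentation","operational_workflow",TRUE
2017-02-10,"TBI","documentation","operational_workflow",TRUE
2017-05-11,"TBI","documentation","unsafe_condition",TRUE
2017-08-10,"TBI","documentation","unsafe_condition",TRUE
2017-11-10,"TBI","documentation","unsafe_condition",TRUE
2018-02-10,"TBI","documentation","unsafe_condition",TRUE
2018-05-11,"TBI","documentation","near_miss",TRUE
2018-08-10,"TBI","documentation","near_miss",TRUE
2018-11-10,"TBI","field_issue","operational_workflow",TRUE
2019-02-10,"TBI","field_issue","operational_workflow",TRUE
2013-02-10,"TBI","field_issue","operational_workflow",TRUE
2013-05-11,"TBI","field_issue","operational_workflow",TRUE
2013-08-10,"TBI","field_issue","operational_workflow",TRUE
2013-11-10,"TBI","field_issue","unsafe_condition",TRUE
2014-02-10,"TBI","field_issue","unsafe_condition",TRUE
2014-05-11,"TBI","field_issue","unsafe_condition",TRUE
2014-08-10,"TBI","field_issue","unsafe_condition",TRUE
2014-11-10,"TBI","field_issue","near_miss",TRUE
2015-02-10,"TBI","field_issue","near_miss",TRUE
2015-05-11,"TBI","field_issue","near_miss",TRUE
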