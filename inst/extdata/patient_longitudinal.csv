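measurement,class,group,timepoint_weeks,value
V1T1,lengths,mediolateral,0,11.0
V1T1,lengths,mediolateral,3,16.3
V1T1,lengths,mediolateral,12,23.3
V1T1,lengths,mediolateral,26,29.4
V2T3,lengths,mediolateral,0,17.5
V2T3,lengths,mediolateral,3,20.9
V2T3,lengths,mediolateral,12,32.7
V2T3,lengths,mediolateral,26,40.8
V3T5,lengths,mediolateral,0,23.9
V3T5,lengths,mediolateral,3,26.7
V3T5,lengths,mediolateral,12,36.3
V3T5,lengths,mediolateral,26,41.5
V4T7,lengths,mediolateral,0,21.5
V4T7,lengths,mediolateral,3,23.0
V4T7,lengths,mediolateral,12,33.6
V4T7,lengths,mediolateral,26,38.5
T1T3,lengths,anteroposterior,0,7.5
T1T3,lengths,anteroposterior,3,9.5
T1T3,lengths,anteroposterior,12,12.2
T1T3,lengths,anteroposterior,26,14.1
T3T5,lengths,anteroposterior,0,12.4
T3T5,lengths,anteroposterior,3,13.2
T3T5,lengths,anteroposterior,12,12.7
T3T5,lengths,anteroposterior,26,11.4
T5T7,lengths,anteroposterior,0,9.0
T5T7,lengths,anteroposterior,3,11.1
T5T7,lengths,anteroposterior,12,14.6
T5T7,lengths,anteroposterior,26,12.9
V1V2T3T1,areas,area,0,119.9
V1V2T3T1,areas,area,3,181.2
V1V2T3T1,areas,area,12,288.9
V1V2T3T1,areas,area,26,384.2
V2V3T5T3,areas,area,0,204.2
V2V3T5T3,areas,area,3,250.6
V2V3T5T3,areas,area,12,363.6
V2V3T5T3,areas,area,26,411.6
V3V4T7T5,areas,area,0,205.7
V3V4T7T5,areas,area,3,248.0
V3V4T7T5,areas,area,12,389.0
V3V4T7T5,areas,area,26,413.7
extension,angles,angle,0,2.3
extension,angles,angle,3,4.6
extension,angles,angle,12,2.0
extension,angles,angle,26,4.0
external_rotation,angles,angle,0,28.4
external_rotation,angles,angle,3,56.4
external_rotation,angles,angle,12,59.1
external_rotation,angles,angle,26,56.9
abduction,angles,angle,0,17.2
abduction,angles,angle,3,9.0
abduction,angles,angle,12,5.2
abduction,angles,angle,26,0.3
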